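# shared fixtures: all built in code, no stored data

saatySet <- c(1:9, 1 / (2:9))

# random reciprocal Saaty matrix of order n (draws from the caller's RNG)
randomReciprocalMatrix <- function(n) {
  A <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sample(saatySet, 1)
      A[i, j] <- d
      A[j, i] <- 1 / d
    }
  }
  comparisonMatrix(A)
}

# fully consistent matrix generated by a weight vector: entries w_i / w_j
consistentMatrix <- function(w) {
  comparisonMatrix(outer(w, w, "/"), labels = names(w))
}

# independent AUC oracle: exhaustive pairwise concordance, ties = 1/2
bruteForceAuc <- function(score, truth) {
  pos <- score[truth]
  neg <- score[!truth]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# independent cutoff oracle: exhaustive Youden scan over observed scores
bruteForceYouden <- function(score, truth) {
  cand <- sort(unique(score))
  j <- vapply(cand, function(t) {
    mean(score[truth] >= t) + mean(score[!truth] < t) - 1
  }, numeric(1))
  min(cand[j == max(j)])
}

# a patient meeting every predicate of the reference form
allPositivePatient <- function() {
  list(gender = "male", stenosis_location = "LAD", ds = 65, tcad = "right",
    lvef = 50, lvm = 150, bmi = 25)
}

# random patient record for property tests (draws from the caller's RNG)
randomPatient <- function() {
  list(
    gender = sample(c("male", "female"), 1),
    stenosis_location = sample(c("LAD", "LCX", "RCA"), 1),
    ds = runif(1, 30, 100),
    tcad = sample(c("left", "right", "balanced"), 1),
    lvef = runif(1, 20, 80),
    lvm = runif(1, 100, 200),
    bmi = runif(1, 15, 35)
  )
}
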