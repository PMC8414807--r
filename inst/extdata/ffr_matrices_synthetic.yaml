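# SYNTHETIC reconstruction: the original pairwise importance-degree matrices
# are not fully published, so these are consistent matrices rebuilt from the
# reference eigenvector weights (entries w_i / w_j). They recover those
# weights exactly, with MCR = n and CI = 0; they are NOT measured data.
schema_version: 1
matrices:
  - name: B
    labels: [clinical statistics, coronary angiography, cardiac ultrasound]
    matrix:
      - [1.00000000000000000, 0.62745098039215685, 1.88235294117647056]
      - [1.59375, 1.00000, 3.00000]
      - [0.53125000000000000, 0.33333333333333337, 1.00000000000000000]
  - name: C1
    labels: [gender, age, hr, sp, dp, bmi]
    matrix:
      - [1.0000000000000000, 3.4999999999999996, 3.7634408602150535, 3.1818181818181817, 3.8461538461538458, 1.3671874999999998]
      - [0.28571428571428575, 1.00000000000000000, 1.07526881720430123, 0.90909090909090917, 1.09890109890109899, 0.39062500000000000]
      - [0.26571428571428574, 0.92999999999999994, 1.00000000000000000, 0.84545454545454546, 1.02197802197802190, 0.36328125000000000]
      - [0.31428571428571433, 1.09999999999999987, 1.18279569892473124, 1.00000000000000000, 1.20879120879120894, 0.42968750000000000]
      - [0.26000000000000001, 0.90999999999999992, 0.97849462365591400, 0.82727272727272727, 1.00000000000000000, 0.35546875000000000]
      - [0.73142857142857154, 2.56000000000000005, 2.75268817204301097, 2.32727272727272716, 2.81318681318681341, 1.00000000000000000]
  - name: C2
    labels: [ls, ds, tcad, cc]
    matrix:
      - [1.00000000000000000, 0.74418604651162779, 1.19008264462809921, 3.46987951807228878]
      - [1.3437500000000002, 1.0000000000000000, 1.5991735537190084, 4.6626506024096388]
      - [0.84027777777777779, 0.62532299741602060, 1.00000000000000000, 2.91566265060240948]
      - [0.28819444444444448, 0.21447028423772610, 0.34297520661157027, 1.00000000000000000]
  - name: C3
    labels: [av, lvef, lvm]
    matrix:
      - [1.00000000000000000, 0.22033898305084748, 0.46428571428571425]
      - [4.5384615384615383, 1.0000000000000000, 2.1071428571428568]
      - [2.15384615384615419, 0.47457627118644075, 1.00000000000000000]
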