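class	SYN_CPG	SYN_TCC	SYN_FLAT	SYN_RANDOM
A[C>A]A	0.003425	0.004438	0.010417	0.020263
A[C>A]C	0.003425	0.004438	0.010417	0.001885
A[C>A]G	0.003425	0.004438	0.010417	0.005584
A[C>A]T	0.003425	0.004438	0.010417	0.00025
C[C>A]A	0.003425	0.004438	0.010417	0.00447
C[C>A]C	0.003425	0.004438	0.010417	0.001496
C[C>A]G	0.003425	0.004438	0.010417	0.030779
C[C>A]T	0.003425	0.004438	0.010417	0.004771
G[C>A]A	0.003425	0.004438	0.010417	0.000281
G[C>A]C	0.003425	0.004438	0.010417	0.024394
G[C>A]G	0.003425	0.004438	0.010417	0.01377
G[C>A]T	0.003425	0.004438	0.010417	0.009394
T[C>A]A	0.003425	0.004438	0.010417	0.014796
T[C>A]C	0.003425	0.004438	0.010417	0.000939
T[C>A]G	0.003425	0.004438	0.010417	0.003204
T[C>A]T	0.003425	0.004438	0.010417	0.029311
A[C>G]A	0.003425	0.004438	0.010417	0.025713
A[C>G]C	0.003425	0.004438	0.010417	0.008208
A[C>G]G	0.003425	0.004438	0.010417	0.007698
A[C>G]T	0.003425	0.004438	0.010417	0.002718
C[C>G]A	0.003425	0.004438	0.010417	0.019168
C[C>G]C	0.003425	0.004438	0.010417	0.032549
C[C>G]G	0.003425	0.004438	0.010417	0.006535
C[C>G]T	0.003425	0.004438	0.010417	0.000746
G[C>G]A	0.003425	0.004438	0.010417	0.009621
G[C>G]C	0.003425	0.004438	0.010417	0.044972
G[C>G]G	0.003425	0.004438	0.010417	0.043226
G[C>G]T	0.003425	0.004438	0.010417	0.012327
T[C>G]A	0.003425	0.004438	0.010417	0.001235
T[C>G]C	0.003425	0.004438	0.010417	0.002138
T[C>G]G	0.003425	0.004438	0.010417	0.000949
T[C>G]T	0.003425	0.004438	0.010417	0.010865
A[C>T]A	0.003425	0.004438	0.010417	0.005507
A[C>T]C	0.003425	0.147929	0.010417	0.007705
A[C>T]G	0.171233	0.004438	0.010417	0.001045
A[C>T]T	0.003425	0.004438	0.010417	0.023352
C[C>T]A	0.003425	0.004438	0.010417	0.011054
C[C>T]C	0.003425	0.147929	0.010417	0.005908
C[C>T]G	0.171233	0.004438	0.010417	0.007467
C[C>T]T	0.003425	0.004438	0.010417	0.011448
G[C>T]A	0.003425	0.004438	0.010417	0.005909
G[C>T]C	0.003425	0.004438	0.010417	0.009045
G[C>T]G	0.171233	0.004438	0.010417	0.003688
G[C>T]T	0.003425	0.004438	0.010417	0.010407
T[C>T]A	0.003425	0.004438	0.010417	0.020684
T[C>T]C	0.003425	0.147929	0.010417	0.001233
T[C>T]G	0.171233	0.004438	0.010417	0.007342
T[C>T]T	0.003425	0.147929	0.010417	0.022692
A[T>A]A	0.003425	0.004438	0.010417	0.006818
A[T>A]C	0.003425	0.004438	0.010417	0.000112
A[T>A]G	0.003425	0.004438	0.010417	0.00036
A[T>A]T	0.003425	0.004438	0.010417	0.012463
C[T>A]A	0.003425	0.004438	0.010417	0.014048
C[T>A]C	0.003425	0.004438	0.010417	0.023664
C[T>A]G	0.003425	0.004438	0.010417	0.000365
C[T>A]T	0.003425	0.004438	0.010417	0.012441
G[T>A]A	0.003425	0.004438	0.010417	0.009212
G[T>A]C	0.003425	0.004438	0.010417	0.000729
G[T>A]G	0.003425	0.004438	0.010417	0.009256
G[T>A]T	0.003425	0.004438	0.010417	0.006204
T[T>A]A	0.003425	0.004438	0.010417	0.000824
T[T>A]C	0.003425	0.004438	0.010417	0.004369
T[T>A]G	0.003425	0.004438	0.010417	0.000711
T[T>A]T	0.003425	0.004438	0.010417	0.003743
A[T>C]A	0.003425	0.004438	0.010417	0.000264
A[T>C]C	0.003425	0.004438	0.010417	0.01306
A[T>C]G	0.003425	0.004438	0.010417	0.020572
A[T>C]T	0.003425	0.004438	0.010417	0.002298
C[T>C]A	0.003425	0.004438	0.010417	0.011306
C[T>C]C	0.003425	0.004438	0.010417	0.01301
C[T>C]G	0.003425	0.004438	0.010417	0.001906
C[T>C]T	0.003425	0.004438	0.010417	0.036644
G[T>C]A	0.003425	0.004438	0.010417	0.00257
G[T>C]C	0.003425	0.004438	0.010417	0.015091
G[T>C]G	0.003425	0.004438	0.010417	0.002814
G[T>C]T	0.003425	0.004438	0.010417	0.005041
T[T>C]A	0.003425	0.004438	0.010417	0.026451
T[T>C]C	0.003425	0.004438	0.010417	0.0142
T[T>C]G	0.003425	0.004438	0.010417	0.000705
T[T>C]T	0.003425	0.004438	0.010417	0.002781
A[T>G]A	0.003425	0.004438	0.010417	0.016832
A[T>G]C	0.003425	0.004438	0.010417	0.071694
A[T>G]G	0.003425	0.004438	0.010417	0.004896
A[T>G]T	0.003425	0.004438	0.010417	0.005211
C[T>G]A	0.003425	0.004438	0.010417	0.000735
C[T>G]C	0.003425	0.004438	0.010417	0.020066
C[T>G]G	0.003425	0.004438	0.010417	0.0077
C[T>G]T	0.003425	0.004438	0.010417	0.000171
G[T>G]A	0.003425	0.004438	0.010417	0.005225
G[T>G]C	0.003425	0.004438	0.010417	0.016814
G[T>G]G	0.003425	0.004438	0.010417	0.021278
G[T>G]T	0.003425	0.004438	0.010417	0.000263
T[T>G]A	0.003425	0.004438	0.010417	0.000258
T[T>G]C	0.003425	0.004438	0.010417	0.00233
T[T>G]G	0.003425	0.004438	0.010417	0.003029
T[T>G]T	0.003425	0.004438	0.010417	0.000724
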