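P,I,V,replicate,y
H,D,S,1,1.50387
H,D,S,2,1.92858
H,D,S,3,1.62299
H,D,S,4,1.66773
H,D,S,5,1.19687
L,D,S,1,0.38778
L,D,S,2,0.85134
L,D,S,3,0.81318
L,D,S,4,0.73963
L,D,S,5,0.49529
H,B,S,1,1.60825
H,B,S,2,2.01751
H,B,S,3,1.57881
H,B,S,4,2.03325
H,B,S,5,2.07528
L,B,S,1,1.29956
L,B,S,2,2.10515
L,B,S,3,2.01212
L,B,S,4,2.13537
L,B,S,5,1.21208
H,D,F,1,1.03956
H,D,F,2,1.87325
H,D,F,3,1.28097
H,D,F,4,2.05677
H,D,F,5,1.23608
L,D,F,1,0.59557
L,D,F,2,0.6833
L,D,F,3,0.40825
L,D,F,4,0.865
L,D,F,5,0.41577
H,B,F,1,2.34357
H,B,F,2,2.30503
H,B,F,3,1.07387
H,B,F,4,1.79348
H,B,F,5,1.15578
L,B,F,1,1.71166
L,B,F,2,1.40724
L,B,F,3,1.6009
L,B,F,4,1.54427
L,B,F,5,1.17839
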