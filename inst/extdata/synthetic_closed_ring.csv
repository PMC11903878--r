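spoke,x,y,z
2,88.545603,46.472317,8.461538
3,56.806475,82.298387,16.923077
4,12.053668,99.270887,25.384615
5,-35.460489,93.501624,33.846154
6,-74.851075,66.312266,42.307692
7,-97.094182,23.931566,50.769231
8,-97.094182,-23.931566,59.230769
9,-74.851075,-66.312266,67.692308
10,-35.460489,-93.501624,76.153846
11,12.053668,-99.270887,84.615385
12,56.806475,-82.298387,93.076923
13,88.545603,-46.472317,101.538462
14,100.000000,0.000000,110.000000
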