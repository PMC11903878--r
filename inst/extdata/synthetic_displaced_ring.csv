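spoke,x,y,z
1,95.206976,41.571967,-22.783637
2,68.426993,75.836212,-1.074855
3,29.389691,90.976767,23.609751
4,-12.292530,83.378203,47.428471
5,-46.401351,54.634349,66.737958
6,-64.453427,11.183163,78.927878
7,-61.643821,-37.168122,83.018902
8,-37.946754,-79.489720,79.887063
9,1.878486,-106.233176,72.063061
10,49.377840,-111.418796,63.152518
11,94.339205,-94.005529,57.009967
12,127.131898,-58.129455,56.855828
13,150.297670,-11.902344,61.094489
14,141.515363,38.092431,77.433258
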