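# synthetic 3Di-style substitution matrix (generated; not the Foldseek matrix)
  A  C  D  E  F  G  H  I  K  L  M  N  P  Q  R  S  T  V  W  Y
A  12   2  -3   2  -4   2  -1   0  -2  -2  -4  -1  -4  -3  -2   0  -2  -2  -1  -2
C   2   6  -2  -2  -1  -4  -4   1  -2   1  -1  -2  -2  -2  -4  -2  -4   1  -4  -6
D  -3  -2   8  -2  -4  -3  -2  -3  -2  -6   0  -2  -5  -4  -2   0  -4  -2  -2  -5
E   2  -2  -2   8  -1  -3  -4  -4  -3   1  -2  -6  -2  -1  -3  -2  -4  -2  -4   0
F  -4  -1  -4  -1   7  -4  -2  -2  -5  -2  -2  -2  -4  -2  -1  -4  -5   0   0   0
G   2  -4  -3  -3  -4   8   0   1   0  -2  -2  -2  -4   0  -2   0  -4  -2   1  -1
H  -1  -4  -2  -4  -2   0  10  -2   0  -4  -2  -2  -2  -2  -5  -2  -5  -4  -6  -4
I   0   1  -3  -4  -2   1  -2  10  -2   0  -2   0  -4  -2   0  -2   0   1  -2  -4
K  -2  -2  -2  -3  -5   0   0  -2  10   0  -2  -2  -1  -2  -1   0  -2   0   0  -2
L  -2   1  -6   1  -2  -2  -4   0   0   7  -1   2  -3  -2  -4   0  -3   0  -5  -4
M  -4  -1   0  -2  -2  -2  -2  -2  -2  -1   8   0  -4   0   0  -2  -4  -1  -2  -2
N  -1  -2  -2  -6  -2  -2  -2   0  -2   2   0  12  -2  -2  -2  -5  -2  -4   2   0
P  -4  -2  -5  -2  -4  -4  -2  -4  -1  -3  -4  -2   9  -2   0  -4   1  -3  -3  -2
Q  -3  -2  -4  -1  -2   0  -2  -2  -2  -2   0  -2  -2   7  -2  -4  -3  -2  -2   0
R  -2  -4  -2  -3  -1  -2  -5   0  -1  -4   0  -2   0  -2   7   0  -2  -2  -1  -4
S   0  -2   0  -2  -4   0  -2  -2   0   0  -2  -5  -4  -4   0   9   0  -4  -3  -4
T  -2  -4  -4  -4  -5  -4  -5   0  -2  -3  -4  -2   1  -3  -2   0   9  -4  -2  -2
V  -2   1  -2  -2   0  -2  -4   1   0   0  -1  -4  -3  -2  -2  -4  -4   8  -5  -5
W  -1  -4  -2  -4   0   1  -6  -2   0  -5  -2   2  -3  -2  -1  -3  -2  -5   4  -2
Y  -2  -6  -5   0   0  -1  -4  -4  -2  -4  -2   0  -2   0  -4  -4  -2  -5  -2   9
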