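# Synthetic 5x5 binary digit font (reconstruction, classic pixel style).
# Constraints: every digit carries a contiguous run of >= 3 "on" pixels in
# some row or column; digits 2 and 5 are exact mirror images whose inner
# columns read 10111 / 11101.
digit: 0
01110
10001
10001
10001
01110

digit: 1
00100
01100
00100
00100
01110

digit: 2
11110
00010
01110
01000
01111

digit: 3
01110
00010
01110
00010
01110

digit: 4
00010
00110
01010
11111
00010

digit: 5
01111
01000
01110
00010
11110

digit: 6
00110
01000
01110
01010
01110

digit: 7
01110
00010
00100
01000
01000

digit: 8
01110
10001
01110
10001
01110

digit: 9
01110
01010
01110
00010
01110
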