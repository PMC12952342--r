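pt,pn,pm,stage
1,0,0,1
1,0,1,4
1,1,0,3
1,1,1,4
1,2,0,3
1,2,1,4
2,0,0,1
2,0,1,4
2,1,0,3
2,1,1,4
2,2,0,3
2,2,1,4
3,0,0,2
3,0,1,4
3,1,0,3
3,1,1,4
3,2,0,3
3,2,1,4
4,0,0,2
4,0,1,4
4,1,0,3
4,1,1,4
4,2,0,3
4,2,1,4
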