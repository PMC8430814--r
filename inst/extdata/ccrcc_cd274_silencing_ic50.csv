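cell_line,group,replicate,ic50
786-O,P-SCR,A,5.9
786-O,P-SCR,B,3.8
786-O,P-SCR,C,4.7
786-O,P-siRNA,A,4.2
786-O,P-siRNA,B,4.9
786-O,P-siRNA,C,6.8
786-O,c1-SCR,A,11.0
786-O,c1-SCR,B,11.7
786-O,c1-SCR,C,12.3
786-O,c1-siRNA,A,6.5
786-O,c1-siRNA,B,9.6
786-O,c1-siRNA,C,9.5
786-O,c2-SCR,A,10.6
786-O,c2-SCR,B,8.2
786-O,c2-SCR,C,9.4
786-O,c2-siRNA,A,6.6
786-O,c2-siRNA,B,6.5
786-O,c2-siRNA,C,8.0
A498,P-SCR,A,5.5
A498,P-SCR,B,9.8
A498,P-SCR,C,14.1
A498,P-siRNA,A,6.31
A498,P-siRNA,B,11.8
A498,P-siRNA,C,14.8
A498,c1-SCR,A,6.7
A498,c1-SCR,B,10.6
A498,c1-SCR,C,13
A498,c1-siRNA,A,7.7
A498,c1-siRNA,B,12.8
A498,c1-siRNA,C,15.4
A498,c2-SCR,A,9.6
A498,c2-SCR,B,10.2
A498,c2-SCR,C,15.3
A498,c2-siRNA,A,13.3
A498,c2-siRNA,B,11.4
A498,c2-siRNA,C,20.6
Caki-1,P-SCR,A,9.3
Caki-1,P-SCR,B,6.4
Caki-1,P-SCR,C,9.7
Caki-1,P-siRNA,A,10.8
Caki-1,P-siRNA,B,6.7
Caki-1,P-siRNA,C,9.2
Caki-1,c1-SCR,A,9
Caki-1,c1-SCR,B,9.5
Caki-1,c1-SCR,C,11
Caki-1,c1-siRNA,A,11.4
Caki-1,c1-siRNA,B,16.1
Caki-1,c1-siRNA,C,11.4
Caki-1,c2-SCR,A,10
Caki-1,c2-SCR,B,11
Caki-1,c2-SCR,C,12
Caki-1,c2-siRNA,A,11.5
Caki-1,c2-siRNA,B,11.9
Caki-1,c2-siRNA,C,12.4
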