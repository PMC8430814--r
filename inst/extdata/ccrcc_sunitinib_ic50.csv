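cell_line,group,replicate,ic50
786-O,parental,A,5.7
786-O,parental,B,11.39
786-O,parental,C,6.7
786-O,c1,A,17.32
786-O,c1,B,23.3
786-O,c1,C,20.4
786-O,c2,A,13.54
786-O,c2,B,20.07
786-O,c2,C,12.8
A498,parental,A,10.48
A498,parental,B,7.682
A498,parental,C,7.18
A498,c1,A,11.92
A498,c1,B,12.42
A498,c1,C,12.01
A498,c2,A,14.36
A498,c2,B,16.04
A498,c2,C,10.54
Caki-1,parental,A,9.5
Caki-1,parental,B,9
Caki-1,parental,C,12.2
Caki-1,c1,A,16.8
Caki-1,c1,B,14.6
Caki-1,c1,C,16.2
Caki-1,c2,A,18
Caki-1,c2,B,17.3
Caki-1,c2,C,14.7
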