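feature_kind,cell_line,n_c1,n_c2,n_common
miRNA,786-O,253,234,184
miRNA,A498,102,107,51
miRNA,Caki-1,678,514,273
gene,786-O,2608,2029,1383
gene,A498,1523,1411,621
gene,Caki-1,2905,2370,990
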