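ncols 24
nrows 24
nodata_value -9999
5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 60 60 60 5 5 5 5 5
5 5 5 5 5 5 5 5 5 5 5 5 5 5 60 95 95 95 60 5 5 5 5 5
5 5 5 5 5 5 5 5 5 5 5 5 5 5 60 95 95 95 5 5 5 5 5 5
5 5 5 5 5 5 5 5 5 5 5 5 5 5 60 95 95 95 60 5 5 5 5 5
5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 60 60 60 5 5 5 5 5 5
5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5
5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5
5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5
5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5
5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5
5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5
5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5
5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5
5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5
5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5
5 5 5 60 5 60 60 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5
5 5 5 60 95 95 60 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5
5 5 5 5 95 95 60 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5
5 5 5 5 5 60 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5
5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5
5 5 5 5 5 5 5 5 5 5 60 60 60 5 5 5 5 5 5 5 5 5 5 5
5 5 5 5 5 5 5 5 5 5 60 95 60 5 5 5 5 5 5 5 5 5 5 5
5 5 5 5 5 5 5 5 5 5 60 60 60 5 5 5 5 5 5 5 5 5 5 5
5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5 5
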