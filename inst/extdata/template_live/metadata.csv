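key,value
cell_line_name,demo epithelial line
media,standard growth medium
notes,template dataset: one untreated culture with three replicates
time_unit,h
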