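#uo_id,2
#design,ofat
#factors,load_pH
#slc,hcp,124146.325947852
run_id,load_pH,response_hcp,scale
R01,6.8,139.818675694896,small
R02,7,103.477769868286,small
R03,7.2,177.631607435269,small
R04,7.4,150.477030394561,small
R05,7.6,159.200506548891,small
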