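#uo_id,6
#design,grid5x3
#factors,elu_cond,elu_pH
#slc,hcp,27.9164521225287
#slc,monomer,97.8495386051958
run_id,elu_cond,elu_pH,response_hcp,response_aggregates,response_monomer,scale
R01,10,5,7.4762987882574,1.301679571411,1.00173172381647,small
R02,12,5,8.00091260725478,1.28432761183078,1.00081917260584,small
R03,14,5,11.385416552772,1.6043845192864,1.00042470721181,small
R04,10,5.5,5.50247272637788,1.151021928564,1.00188447465527,small
R05,12,5.5,7.12705394670491,1.13989378752783,1.00390258833072,small
R06,14,5.5,9.79952155274666,1.94246923925207,1.00115361453896,small
R07,10,6,4.35017988296077,1.40483191948254,1.00218538468017,small
R08,12,6,5.63010530732334,1.22386740521251,1.002551008805,small
R09,14,6,7.77066426048212,1.80541414349418,1.00340715615303,small
R10,11,5.5,5.86334450474779,1.39096588799958,1.00141793246422,small
R11,13,5.5,8.88027099897158,1.53344752409448,1.00160150744822,small
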