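#uo_id,8
#design,ccf
#factors,hic_pH,hic_cond,hic_temp
run_id,hic_pH,hic_cond,hic_temp,response_aggregates,response_monomer,scale
R01,6.4,6,18,1.23717314878663,1.00157130455558,small
R02,7.2,6,18,1.48702383704334,1.00121120103393,small
R03,6.4,10,18,0.942178541326687,1.00072910358951,small
R04,7.2,10,18,1.70252114098089,1.0038699872903,small
R05,6.4,6,26,1.67323343543589,0.999899847404812,small
R06,7.2,6,26,1.59531395386185,1.00244795078862,small
R07,6.4,10,26,1.0900113011573,1.0024735842934,small
R08,7.2,10,26,1.41171895836422,1.00356813047814,small
R09,7.2,8,22,1.54961762961704,1.00369814451197,small
R10,6.8,10,22,1.08424664307424,1.00286824859786,small
R11,6.8,8,26,1.29441512087654,1.00139338281963,small
R12,6.4,8,22,1.0853992025274,1.00118730660051,small
R13,6.8,6,22,1.36643082386547,1.00229589546491,small
R14,6.8,8,18,1.43560979866782,1.00231831322095,small
R15,6.8,8,22,1.46838590845632,1.00231762329862,small
R16,6.8,8,22,1.41590919525667,1.00163422074077,small
R17,6.8,8,22,1.33371072226035,1.00282889461703,small
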