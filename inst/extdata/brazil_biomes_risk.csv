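region,nfdc_class,subregion,risk_ssp245_2050,risk_ssp245_2090,risk_ssp585_2050,risk_ssp585_2090
Cerrado,fire-dependent,FALSE,160.16,377.90,320.91,1235.23
Pampa,fire-dependent,FALSE,0.00,83.50,68.06,538.61
Pantanal,fire-dependent,FALSE,93.06,211.07,142.59,717.07
Caatinga,fire-independent,FALSE,184.36,536.98,394.15,1354.51
Amazon,fire-sensitive,FALSE,10.91,45.07,39.74,186.13
Atlantic Forest,fire-sensitive,FALSE,559.14,992.08,941.82,3671.60
Atlantic Forest NE,fire-sensitive,TRUE,916.05,1591.36,1576.02,5787.16
Atlantic Forest SE,fire-sensitive,TRUE,284.26,533.92,450.07,2064.99
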