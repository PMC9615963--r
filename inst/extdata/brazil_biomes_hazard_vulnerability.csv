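region,nfdc_class,subregion,hazard_ssp245_2050,hazard_ssp245_2090,hazard_ssp585_2050,hazard_ssp585_2090,resilience,vi
Cerrado,fire-dependent,FALSE,13.66,32.23,27.37,105.35,0.73,11.73
Pampa,fire-dependent,FALSE,0.00,6.22,5.07,40.12,0.75,13.43
Pantanal,fire-dependent,FALSE,14.54,32.98,22.28,112.04,0.67,6.40
Caatinga,fire-independent,FALSE,16.96,49.40,36.26,124.61,0.70,10.87
Amazon,fire-sensitive,FALSE,8.20,33.89,29.88,139.95,0.54,1.33
Atlantic Forest,fire-sensitive,FALSE,28.76,51.02,48.44,188.82,0.92,19.45
Atlantic Forest NE,fire-sensitive,TRUE,42.39,73.64,72.93,267.80,0.92,21.61
Atlantic Forest SE,fire-sensitive,TRUE,15.12,28.40,23.94,109.84,0.93,18.80
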