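region,g_co2_per_kwh
US,395.93
CA,130.00
GB,225.00
FR,56.00
DE,350.00
EU,276.00
IN,708.00
PK,440.00
CN,582.00
AU,510.00
GLOBAL,475.00
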