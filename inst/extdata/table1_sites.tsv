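site_id	depth_m	depth_category	effort_min	coverage_pct
reef01	2.4	shallow	31.43	85
reef02	2.6	shallow	23.80	83
reef03	7.7	shallow	40.07	89
reef04	9.1	shallow	44.50	89
reef05	9.3	shallow	33.88	98
reef14	18	shallow	19.68	72
reef06	20.1	shallow	28.15	86
reef07	24.5	shallow	24.32	80
reef08	30	deep	23.05	75
reef09	30	deep	26.27	96
reef10	30	deep	31.83	99
reef11	33	deep	37.72	96
reef12	33	deep	34.47	98
reef13	33	deep	28.40	93
reef15	34	deep	70.32	89
reef16	35	deep	23.50	69
reef17	35	deep	20.50	93
reef18	40	deep	26.03	95
reef19	44.7	deep	105.02	96
reef20	48	deep	35.43	95
reef21	54.4	deep	66.08	89
reef22	62.3	deep	53.15	97
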