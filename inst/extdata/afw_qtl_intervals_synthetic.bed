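# Synthetic stand-in QTL intervals (BED, 0-based half-open) for the abdominal-fat
# QTL annotation demonstration; ids follow the QTL-database numbering cited in
# the study design, coordinates are constructed, not downloaded.
27	900000	1400000	QTL_11809
27	1000000	1500000	QTL_11817
3	34000000	36500000	QTL_9418
3	35000000	36000000	QTL_1958
3	34500000	35800000	QTL_11816
Z	59000000	60500000	QTL_2268
Z	59500000	60200000	QTL_12633
1	31500000	32500000	QTL_3353
13	14000000	15500000	QTL_12630
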