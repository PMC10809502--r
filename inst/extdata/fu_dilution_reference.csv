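compound_id,fu_brain_determined_pct,fu_bsa35_determined_pct,fu_brain_predicted_pct,fu_bsa35_predicted_pct
altanserin,22.9,45.1,22.1,26.8
antipyrine,84.3,>100,>100,99.9
atenolol,95.2,>100,>100,99.9
buspirone,83.6,84.2,83.1,90.4
cimetidine,93.8,>100,95.6,99.2
citalopram,51.3,97.3,47.9,96.0
diphenhydramine,62.6,>100,72.8,94.7
doxepin,24.8,92.2,33.0,87.1
fluoxetine,5.2,66.0,5.7,70.6
gabapentin,94.6,98.4,93.4,99.8
indomethacin,35.8,19.6,42.8,38.2
metoclopramide,87.8,>100,90.7,98.8
n_desmethylclozapine,13.1,89.2,13.9,82.1
propranolol,35.0,89.7,37.4,86.8
risperidone,74.5,91.8,69.9,89.4
way_100635,74.8,80.2,71.8,87.1
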