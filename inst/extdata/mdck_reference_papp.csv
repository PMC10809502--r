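compound_id,papp_atob_1e6_cm_s,papp_btoa_1e6_cm_s,er_reported,pgp_class_reported,permeability_class_reported
altanserin,3.0,3.4,1.1,unlikely,moderate
antipyrine,39,48,1.2,unlikely,high
atenolol,NA,NA,NA,not_available,low
buspirone,21,20,0.9,unlikely,high
cimetidine,NA,2.5,NA,possible,low
citalopram,4.7,7.7,1.7,possible,moderate
diphenhydramine,9.8,16,1.6,possible,moderate
doxepin,2.0,2.2,1.1,unlikely,moderate
fluoxetine,0.4,0.4,1.0,unlikely,low
gabapentin,2.9,1.6,0.5,unlikely,moderate
indomethacin,3.7,2.7,0.7,unlikely,moderate
metoclopramide,24,49,2.0,likely,high
n_desmethylclozapine,2.1,4.4,2.1,likely,moderate
n_desmethylclozapine_inhibitor,3.6,2.9,0.8,unlikely,moderate
propranolol,4.5,3.7,0.8,unlikely,moderate
risperidone,8.5,37,4.4,likely,moderate
way_100635,13,17,1.3,unlikely,high
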