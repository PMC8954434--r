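species_id,region_label,large_fruit,indigenous_use,signal1,signal2,signal3,signal4,starred
C. australe,CYP/AWT,TRUE,TRUE,not_detected,detected,not_detected,not_detected,FALSE
C. australe,SEQ/NNSW,TRUE,TRUE,detected,detected,not_detected,not_detected,TRUE
E. insignis,NA,TRUE,TRUE,not_detected,not_detected,not_detected,detected,TRUE
B. bancroftii,NA,TRUE,TRUE,detected,not_detected,detected,detected,TRUE
P. australis,NA,TRUE,TRUE,not_detected,not_detected,detected,not_detected,FALSE
E. bancroftii,NA,TRUE,TRUE,detected,detected,not_detected,not_assessable,TRUE
E. globosa,AWT,TRUE,FALSE,not_detected,not_detected,detected,not_detected,FALSE
E. globosa,NNSW,TRUE,FALSE,not_assessable,not_assessable,detected,not_detected,FALSE
E. compressa,NA,TRUE,FALSE,not_detected,not_detected,not_detected,not_detected,FALSE
E. pubens,NA,TRUE,FALSE,not_detected,not_detected,not_detected,not_detected,FALSE
N. prunifera,NA,TRUE,FALSE,not_detected,not_detected,not_detected,detected,TRUE
N. whitei,NA,TRUE,FALSE,not_detected,not_detected,not_detected,not_detected,FALSE
E. johnsonii,NA,TRUE,FALSE,not_detected,not_detected,detected,not_assessable,FALSE
E. grandis,NA,FALSE,TRUE,detected,not_detected,detected,not_assessable,FALSE
E. discolor,NA,FALSE,FALSE,detected,detected,not_detected,detected,FALSE
P. queenslandica,NA,FALSE,FALSE,not_detected,detected,not_detected,detected,FALSE
E. reticulatus,NA,FALSE,FALSE,not_detected,not_detected,not_detected,not_assessable,FALSE
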