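event_code,name
EV01,acute myocardial infarction
EV02,acute liver injury
EV03,acute renal failure
EV04,anaphylactic shock
EV05,rhabdomyolysis
EV06,upper gastrointestinal bleeding
EV07,cardiac arrhythmia
EV08,neutropenia
EV09,pancytopenia
EV10,erythema multiforme
EV11,confusional state
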