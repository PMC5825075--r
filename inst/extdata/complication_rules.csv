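name,inclusion_codes,exclusion_codes,exclusion_scope
urinary_tract_infection,N390,N10;N11;N12;N13;N15;N20;N21;N23;N30;N31;N32;N33;N34;N35;N36,principal_only
pressure_injury,L89,G81;G82;G041;G114;T913,principal_or_additional
pneumonia,J13;J14;J15;J16;J18,D80;D81;D82;D83;D84;E84;J17,principal_or_additional
delirium,F05,F10;F11;F12;F13;F14;F15;F16;F18;F19,principal_or_additional
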