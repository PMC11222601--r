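case_id,score_dsa,score_combined,truth
E001,5,5,unknown
E002,5,5,unknown
E003,5,5,unknown
E004,5,5,unknown
E005,5,5,unknown
E006,5,5,unknown
E007,5,5,unknown
E008,5,5,unknown
E009,5,5,unknown
E010,5,5,unknown
E011,5,5,unknown
E012,4,5,unknown
E013,4,5,unknown
E014,4,5,unknown
E015,4,5,unknown
E016,4,5,unknown
E017,4,5,unknown
E018,4,5,unknown
E019,4,3,unknown
E020,4,3,unknown
E021,3,5,unknown
E022,3,4,unknown
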