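case_id,score_dsa,score_combined,truth
N001,1,1,no_bleeding
N002,1,1,no_bleeding
N003,1,1,no_bleeding
N004,1,1,no_bleeding
N005,1,1,no_bleeding
N006,1,1,no_bleeding
N007,1,1,no_bleeding
N008,1,1,no_bleeding
N009,1,1,no_bleeding
N010,1,1,no_bleeding
N011,1,1,no_bleeding
N012,1,1,no_bleeding
N013,1,1,no_bleeding
N014,1,1,no_bleeding
N015,1,1,no_bleeding
N016,1,1,no_bleeding
N017,1,1,no_bleeding
N018,1,1,no_bleeding
N019,1,1,no_bleeding
N020,1,1,no_bleeding
N021,1,1,no_bleeding
N022,2,1,no_bleeding
N023,2,1,no_bleeding
N024,2,1,no_bleeding
N025,2,1,no_bleeding
N026,2,1,no_bleeding
N027,2,1,no_bleeding
N028,2,1,no_bleeding
N029,2,1,no_bleeding
N030,2,1,no_bleeding
N031,2,1,no_bleeding
N032,2,1,no_bleeding
N033,2,1,no_bleeding
N034,2,1,no_bleeding
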