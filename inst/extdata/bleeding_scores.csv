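case_id,score_dsa,score_combined,truth
B001,5,5,bleeding
B002,5,5,bleeding
B003,5,5,bleeding
B004,5,5,bleeding
B005,5,5,bleeding
B006,5,5,bleeding
B007,5,5,bleeding
B008,5,5,bleeding
B009,5,5,bleeding
B010,5,5,bleeding
B011,5,5,bleeding
B012,5,5,bleeding
B013,5,5,bleeding
B014,5,5,bleeding
B015,5,5,bleeding
B016,5,5,bleeding
B017,5,5,bleeding
B018,5,5,bleeding
B019,5,5,bleeding
B020,5,5,bleeding
B021,5,5,bleeding
B022,5,5,bleeding
B023,5,5,bleeding
B024,5,5,bleeding
B025,5,5,bleeding
B026,5,5,bleeding
B027,5,5,bleeding
B028,5,5,bleeding
B029,5,5,bleeding
B030,5,5,bleeding
B031,5,5,bleeding
B032,5,5,bleeding
B033,5,5,bleeding
B034,5,5,bleeding
B035,5,5,bleeding
B036,5,5,bleeding
B037,5,5,bleeding
B038,5,5,bleeding
B039,5,5,bleeding
B040,5,5,bleeding
B041,5,5,bleeding
B042,5,5,bleeding
B043,5,5,bleeding
B044,5,5,bleeding
B045,5,5,bleeding
B046,5,5,bleeding
B047,4,5,bleeding
B048,4,5,bleeding
B049,4,5,bleeding
B050,4,5,bleeding
B051,4,5,bleeding
B052,4,5,bleeding
B053,4,5,bleeding
B054,4,5,bleeding
B055,4,5,bleeding
B056,4,5,bleeding
B057,4,5,bleeding
B058,4,5,bleeding
B059,4,5,bleeding
B060,4,5,bleeding
B061,4,5,bleeding
B062,4,5,bleeding
B063,4,5,bleeding
B064,4,5,bleeding
B065,4,5,bleeding
B066,4,5,bleeding
B067,4,5,bleeding
B068,4,5,bleeding
B069,4,5,bleeding
B070,4,5,bleeding
B071,4,5,bleeding
B072,4,5,bleeding
B073,4,5,bleeding
B074,4,5,bleeding
B075,4,4,bleeding
B076,4,4,bleeding
B077,4,4,bleeding
B078,4,4,bleeding
B079,4,4,bleeding
B080,4,4,bleeding
B081,4,4,bleeding
B082,4,4,bleeding
B083,4,4,bleeding
B084,4,4,bleeding
B085,4,4,bleeding
B086,4,4,bleeding
B087,4,4,bleeding
B088,4,4,bleeding
B089,4,4,bleeding
B090,4,4,bleeding
B091,4,4,bleeding
B092,4,4,bleeding
B093,4,4,bleeding
B094,4,4,bleeding
B095,3,4,bleeding
B096,3,4,bleeding
B097,3,4,bleeding
B098,3,4,bleeding
B099,3,4,bleeding
B100,3,4,bleeding
B101,3,4,bleeding
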