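(sp_001,sp_002,(((sp_003,sp_004,sp_005),(sp_006,sp_007)),((sp_008,sp_009),(sp_010,sp_011),sp_012),sp_013),((((sp_014,sp_015),sp_016),sp_017),(sp_018,sp_019,sp_020,(sp_021,(sp_022,sp_023))),sp_024));
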