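locus	strategy	pct_precise
OsGRF4	PE3	8.3
OsGRF4	PDel	12.5
OsALS	PE3	50
OsALS	PDel	75
OsGS3	PDel	61.4
OsWaxy-E	PDel	69
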