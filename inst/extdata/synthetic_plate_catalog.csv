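well,species,strain,growth_phase,replicate_group,plate_format,depth_mm
A1,synthetic mixed sinker,NA,stationary,mix_stat,96,NA
A2,synthetic mixed sinker,NA,stationary,mix_stat,96,NA
A3,synthetic mixed sinker,NA,stationary,mix_stat,96,NA
B1,synthetic slow sinker,NA,exponential,slow_expo,96,NA
B2,synthetic slow sinker,NA,exponential,slow_expo,96,NA
B3,synthetic slow sinker,NA,exponential,slow_expo,96,NA
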