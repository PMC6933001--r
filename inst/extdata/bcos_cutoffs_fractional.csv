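task,band_le64,band_65_74,band_ge75
gesture_production,11.5,11.5,11.5
gesture_recognition,5.8,5.8,5.8
gesture_imitation,11.5,11.5,11.5
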