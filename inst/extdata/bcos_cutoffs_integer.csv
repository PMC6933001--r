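task,band_le64,band_65_74,band_ge75
gesture_production,10,9,9
gesture_recognition,5,5,4
gesture_imitation,9,9,9
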