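{"grid":{"beat_rate":2,"subdivisions_per_beat":2,"beats_per_measure":4,"n_measures":4},"onsets":[0,3,8,12,16,19,24,27]}
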