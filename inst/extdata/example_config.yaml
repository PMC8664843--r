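# Example pipeline configuration: the literature-mode filter settings with
# the severity-task chunk overlap. Load with read_config().
rms_window_ms: 500
chunk_s: 10
overlap: 0.5
pnn50_denominator: total
sd2_convention: as_printed
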