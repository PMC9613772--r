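# column medians without the apply/median overhead (compiled hot path)
col_medians <- function(m) col_medians_cpp(m)
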