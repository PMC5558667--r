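# Intron distribution pattern catalog for the bHLH domain.
# positions: comma-separated profile indices; phases optional ('' = ignore).
# Only pattern IV (introns at His-9 and Val-31) is published verbatim; add
# further patterns (I-XII) here as needed, or use pattern discovery mode.
pattern_id	positions	phases	position_labels
IV	9,31		His-9,Val-31
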