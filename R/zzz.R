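## Package code subsets data.tables with logical/expression i.
.datatable.aware <- TRUE
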