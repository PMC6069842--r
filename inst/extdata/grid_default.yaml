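# Illustrative grid of pipeline arguments: the value lists cover the ranges
# these arguments are commonly swept over, but no claim is made that this
# factorization matches any particular published grid run.
align_scope: [global, local]
align_sensitivity: [sensitive, very-sensitive]
bam_processor: [plain, dedup]
peak_size: [10, 60, 200, 500, 1000, 2000]
min_dist: [0, 50, 500]
footprinter: [hint, wellington]
hint_bias_mode: [none, known-enzyme, estimated]
wellington_p_cutoff: [0.01, 0.001]
wellington_fdr: [0.01, 0.05]
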