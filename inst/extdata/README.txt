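hg38_arms.tsv: approximate hg38-like chromosome-arm boundaries (rounded
chromosome lengths and centromere midpoints); suitable for examples and
tests, not for production coordinate lookups.
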