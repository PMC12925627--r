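# example aligned CDEI-like sites, one per line
GTCACGTG
ATCACGTG
GTCACGTG
GTCACGTG
GTCACGTG
GTCACGTG
GTCACGTG
GTCACGTG
ATCACGTG
GTCAAGTG
GTCACATG
GTCACGTG
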