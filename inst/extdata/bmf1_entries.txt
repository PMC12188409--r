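# Reference set of bovine mitochondrial F1 crystal structures.
# copies: number of F1 complexes in the asymmetric unit of the entry.
# inhibitorBound: whether the entry carries a bound inhibitor protein chain.
id,copies,inhibitorBound
1bmf,1,FALSE
1cow,1,FALSE
1e1q,1,FALSE
1e1r,1,FALSE
1e79,1,FALSE
1efr,1,FALSE
1h8e,1,FALSE
1h8h,1,FALSE
1nbm,1,FALSE
1ohh,1,TRUE
1w0j,1,FALSE
1w0k,1,FALSE
2ck3,1,FALSE
2jdi,1,FALSE
2jiz,2,FALSE
2jj1,2,FALSE
2jj2,2,FALSE
2v7q,1,TRUE
4asu,1,FALSE
4tsf,1,TRUE
4tt3,1,TRUE
4yxw,1,FALSE
4z1m,1,TRUE
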