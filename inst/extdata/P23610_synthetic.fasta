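>P23610_synthetic|Homo_sapiens
SGDKEQLNRTSGDKEQLNRTSGDKEQLNRTSGDKEQLNRTSGVAEAGAALGAAALGAAAL
GAAALGAAALGAAALGAAALGAAALGAAALGAAALGAAALGAAALGAAALGAAALGAAAL
GAAALGAAALGAAALGAAALGAAALGAAALGAAALGAAALGAAALGAAALGAAALGAAAL
GAAALGAAALGAAALGAAALGAAALGAAALGAAALGAAALGAPPPPPPAPQPAALGAAAL
GAAALGAAALGAAALGAALGASGDKEQLNRTSGDKEQLNRTSGDKEQLNRTSGDKEQLNR
TSGDKEQLNRTSGDKEQLNRTSGDKEQLNRTSGDKEQLNRTSGDKEQLNRTSGDKEQLNR
TSGDKEQLNRT
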