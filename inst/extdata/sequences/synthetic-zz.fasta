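>synthetic-zz | tandem Z-domain (ZZ) of S. aureus protein A stand-in (cf. GenBank M74186 / pEZZ18); transcribed offline, not fetched - verify against the accession before quantitative use
VDNKFNKEQQNAFYEILHLPNLNEEQRNAFIQSLKDDPSQSANLLAEAKKLNDAQAPKVD
NKFNKEQQNAFYEILHLPNLNEEQRNAFIQSLKDDPSQSANLLAEAKKLNDAQAPK
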