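>synthetic-angiogenin | mature human angiogenin (123 aa) stand-in (cf. GenBank AAL67710 / UniProt P03950 mature chain); transcribed offline, not fetched - verify against the accession before quantitative use
QDNSRYTHFLTQHYDAKPQGRDDRYCESIMRRRGLTSPCKDINTFIHGNKRSIKAICENK
NGNPHRENLRISKSSFQVTTCKLHGGSPWPPCQYRATAGFRNVVVACENGLPVHLDQSIF
RRP
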