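>M00001|TRBV91-1*01|Homo sapiens|F|V-REGION|demo
GGTACA...CCATGGTT..AACTGA
>M00002|TRBV91-1*02|Homo sapiens|F|V-REGION|demo
GGTACA...CCATGATT..AACTGA
>TRBV91-2*01
GGTTCACCATGGTTAACTGA
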