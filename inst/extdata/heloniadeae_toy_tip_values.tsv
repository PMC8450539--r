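# Synthetic demonstration tip values (1C in Mb). Only the two focal
# Heloniopsis species carry published 1C-values; all other tips and the
# tree itself are synthetic stand-ins for a genus-level phylogeny.
label	value_mb
Helonias_bullata	2950
Ypsilandra_thibetica	3850
Ypsilandra_yunnanensis	3600
Heloniopsis_umbellata	4680
Heloniopsis_orientalis	4100
Heloniopsis_tubiflora	3700
Heloniopsis_koreana	2480
Heloniopsis_leucantha	2700
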