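>ctld_ref_1 c-type lectin domain, synthetic reference 1
CALEDTKNNDWIGLNRIYDKDSTNECDIMFGRDRSTPKKMLQDVNMFEQGLAENRMLTHVEPNVGSSKEIQYLFQSDSGLCQTHYPQALAYEVHVVALPEC
>ctld_ref_2 c-type lectin domain, synthetic reference 2
CALHATKINDWLGLNRIYDKDSTIECDGFFGPDRSPPKKSVQDMNMHEQGLAEIRMATDHEPNVGSKKEIQYLFLSRSILCQTVYPQALAEEVRVQALIEC
>ctld_ref_3 c-type lectin domain, synthetic reference 3
CREEDTLNDTWVGLNRIYDKDSTDFCMAMFMRDRSQPKMDSHDLENFEQMLAENRFNTHVEPNPGSRKEIYYLHQQDSGECQEHYPPALAYEVHTVALEEC
>ctld_ref_4 c-type lectin domain, synthetic reference 4
CALQDTKLNDWIGVNNIKDKGAINSCIIMFGRIRRTPKKILQDHNMFEEMMAENIMLLLVEPNVGSIKEIYFNNFFDSGLCQGHYPEALAYEVHEVALPEC
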