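name	length	notation
ON1	15	5'-ccttttcttttttct-3'
ON2	15	5'-CcTtTtCtTtTtTcT-3'
ON2-Cy3	15	5'-Cy3-cCtTtTcTtTtTtCt-3'
ON2-5'DNA	15	5'-cCtTtTcTtTtTtCt-3'
ON2-3'LNA-reduced	15	5'-CcTtTtCtTttttct-3'
ON2-5'LNA-reduced	15	5'-ccttttCtTtTtTcT-3'
ON2-5'-penultimate-TINA	15	5'-C**P**cTtTtCtTtTtTcT-3'
ON2-center-TINA	15	5'-CcTtTtC**P**tTtTtTcT-3'
ON2-3'-penultimate-TINA	15	5'-CcTtTtCtTtTtTc**P**T-3'
ON3	13	5'-CtTtTcTtTtTtC-3'
ON3-3'LNA-reduced	13	5'-CtTtTcTtTtttc-3'
ON3-5'LNA-reduced	13	5'-ctttTcTtTtTtC-3'
ON3-3'LNA-reduced-c>t	13	5'-TtTtTcTtTtttt-3'
ON3-5'LNA-reduced-c>t	13	5'-ttttTcTtTtTtT-3'
ON3-5'-penultimate-TINA	13	5'-C**P**tTtTcTtTtTtC-3'
ON3-3'-penultimate-TINA	13	5'-CtTtTcTtTtTt**P**C-3'
ON3-5'-ultimate-TINA	13	5'-**P**CtTtTcTtTtTtC-3'
ON3-3'-ultimate-TINA	13	5'-CtTtTcTtTtTtC**P**-3'
ON3-5'-3'-TINA	13	5'-**P**CtTtTcTtTtTtCP-3'
ON4-3'LNA-reduced	15	5'-CtTcTtCtTcttctt-3'
ON4-5'LNA-reduced	15	5'-cttcttCtTcTtCtT-3'
WC29	29	5'-Cy5-tCtTtTtTcTtTtCcCccAcgCccTctGc-3'
bisLNA49	49	5'-Cy3-CcTtTtCtTtTtTcT-tctct-tCtTtTtTcTtTtCcCccAcgCccTctGc-3'
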