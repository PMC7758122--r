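from_pathway,to_pathway,connector,is_feedback
estrogen signaling pathway,NF-kB signaling pathway,ER; Bcl-2,FALSE
estrogen signaling pathway,PI3K-AKT signaling pathway,PIP3; HSP90,FALSE
estrogen signaling pathway,calcium signaling pathway,Ca2+,FALSE
estrogen signaling pathway,cAMP signaling pathway,cAMP,FALSE
estrogen signaling pathway,MAPK signaling pathway,Ras,FALSE
cAMP signaling pathway,PI3K-AKT signaling pathway,cAMP,FALSE
cAMP signaling pathway,calcium signaling pathway,Ca2+,FALSE
cAMP signaling pathway,NF-kB signaling pathway,cAMP,FALSE
cAMP signaling pathway,MAPK signaling pathway,Ras,FALSE
PI3K-AKT signaling pathway,cGMP-PKG signaling pathway,eNOS; NO,FALSE
PI3K-AKT signaling pathway,NF-kB signaling pathway,IKK; IkBa,FALSE
PI3K-AKT signaling pathway,MAPK signaling pathway,Ras,FALSE
cGMP-PKG signaling pathway,calcium signaling pathway,PLCb; IP3R,FALSE
cGMP-PKG signaling pathway,NF-kB signaling pathway,PKG,FALSE
cGMP-PKG signaling pathway,MAPK signaling pathway,Ras,FALSE
calcium signaling pathway,NF-kB signaling pathway,PKC,FALSE
MAPK signaling pathway,NF-kB signaling pathway,Ras,FALSE
calcium signaling pathway,cAMP signaling pathway,Ca2+-dependent AC; PKCtheta,TRUE
NF-kB signaling pathway,PI3K-AKT signaling pathway,IL-1b; TNFa; IkBa,TRUE
NF-kB signaling pathway,estrogen signaling pathway,IL-6; PTGS2; MMPs,TRUE
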