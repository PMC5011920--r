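>H1_ref family=H1 variant=canonical linker histone H1 reference (human H1.2-derived, mature)
SETAPAAPAAAPPAEKAPVKKKAAKKAGGTPRKASGPPVSELITKAVAASKERSGVSLAA
LKKALAAAGYDVEKNNSRIKLGLKSLVSKGTLVQTKGTGASGSFKLNKKAASGEAKPKAK
KAGAAKAKKPAGAAKKPKKATGAATPKKSAKKTPKKAKKPAAAAGAKKAKSPKKAKATKA
KKAPKSPAKAKAVKPKAAKPKTSKPKAAKPKKAAAKKK
>H2A_ref family=H2A variant=canonical core histone H2A reference (human H2A type 1, mature)
SGRGKQGGKARAKAKTRSSRAGLQFPVGRVHRLLRKGNYAERVGAGAPVYLAAVLEYLTA
EILELAGNAARDNKKTRIIPRHLQLAIRNDEELNKLLGKVTIAQGGVLPNIQAVLLPKKT
ESHHKAKGK
>H2AX_ref family=H2A variant=H2A.X H2A.X reference with C-terminal SQEY motif (human, mature)
SGRGKTGGKARAKAKSRSSRAGLQFPVGRVHRLLRKGHYAERVGAGAPVYLAAVLEYLTA
EILELAGNAARDNKKTRIIPRHLQLAIRNDEELNKLLGGVTIAQGGVLPNIQAVLLPKKT
SATVGPKAPSGGKKATQASQEY
>H2AZ_ref family=H2A variant=H2A.Z H2A.Z reference (human H2A.Z-1, mature)
AGGKAGKDSGKAKTKAVSRSQRAGLQFPVGRIHRHLKSRTTSHGRVGATAAVYSAAILEY
LTAEVLELAGNASKDLKVKRITPRHLQLAIRGDEELDSLIKATIAGGGVIPHIHKSLIGK
KGQQKTV
>macroH2A_ref_synthetic family=H2A variant=macroH2A synthetic macroH2A construct: H2A-fold domain plus linker and macro-domain-length extension
SSRGGKKKSTKTSRSAKAGVIFPVGRMLRYIKKGHPKYRIGVGAPVYMAAVLEYLTAEIL
ELAGNAARDNKKGRVTPRHILLAVANDEELNQLLKGVTIASGGVLPNIHPELLAKKRGSK
GKLEAIITPPPAKKAKSPSQKKPVSKKAGGKKGARKSKKKSQLSPGVSEYMVGKREVFLQ
QLAGLDANSERIVSLAGSDRFDAIVHPTNADIDLKDDLGNTLEKKGGKEFVEAVLELRKK
NGPLEVAGAAVSAGHGLPAKFVIHCNSPVWGADKCEELLEKTVKNCLALADDKKLKSIAF
PSIGSGRNGFPKQTAAQLILKAISSYFVSTMSSSIKTVYFVLFDSESIGIYVQEMAKLDA
N
>H2B_ref family=H2B variant=canonical core histone H2B reference (human H2B type 1, mature)
PEPAKSAPAPKKGSKKAVTKAQKKDGKKRKRSRKESYSVYVYKVLKQVHPDTGISSKAMG
IMNSFVNDIFERIAGEASRLAHYNKRSTITSREIQTAVRLLLPGELAKHAVSEGTKAVTK
YTSSK
>H3_ref family=H3 variant=canonical core histone H3 reference (human H3.1, mature; diagnostic-site numbering anchor)
ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALREIRRYQKSTEL
LIRKLPFQRLVREIAQDFKTDLRFQSSAVMALQEACEAYLVGLFEDTNLCAIHAKRVTIM
PKDIQLARRIRGERA
>H33_ref family=H3 variant=H3.3 H3.3 reference (human, mature; S31, AAIG87-90, S96)
ARTKQTARKSTGGKAPRKQLATKAARKSAPSTGGVKKPHRYRPGTVALREIRRYQKSTEL
LIRKLPFQRLVREIAQDFKTDLRFQSAAIGALQEASEAYLVGLFEDTNLCAIHAKRVTIM
PKDIQLARRIRGERA
>CENPA_ref_synthetic family=H3 variant=CENP-A synthetic H3-derived centromeric histone construct (human CENP-A-like)
GPRRRSRKPEAPRRRSPSPTPTPGPSRRGPSLGASSHQHSRRRQGWLKEIRKLQKSTHLL
IRKLPFSRLAREICVKFTRGVDFNWQAQALLALQEAAEAYLVGLFEDAYLCAIHAKRVTI
MPKDIQLARRIRGLEEGLG
>H4_ref family=H4 variant=canonical core histone H4 reference (human, mature)
SGRGKGGKGLGKGGAKRHRKVLRDNIQGITKPAIRRLARRGGVKRISGLIYEETRGVLKV
FLENVIRDAVTYTEHAKRKTVTAMDVVYALKRQGRTLYGFGG
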