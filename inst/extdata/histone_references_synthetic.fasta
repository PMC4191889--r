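>ceH2A species=celegans family=H2A synthetic stand-in histone sequence
MSGRGKGGKAKAKAKTRSSRAGLQFPVGRVHRLLRKGNYSERVGGGAGAPVYLAAVLEYL
TAEILELAGNAARDNKKTRIIPRHLQLAIRNDEELNKLLGRVTIAQGGVLPNIQAVLLPK
KTESHHKAKGK
>ceH2B species=celegans family=H2B synthetic stand-in histone sequence
MPPKTSAKGAKKAGKAQKNITKDGKKRKRSRKESYSVYVYKVLKQVHPDTGISSKAMSIM
NSFVNDVFERIAGEASRLAHYNKRSTITSREIQTAVRLLLPGELAKHAVSEGTKAVTKYT
SAK
>ceH3 species=celegans family=H3 synthetic stand-in histone sequence
MARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALREIRRYQKSTE
LLIRKLPFQRLVREIAQDFKTDLRFQSSAVMALQEASEAYLVGLFEDTNLCAIHAKRVTI
MPKDIQLARRIRGERA
>ceH4 species=celegans family=H4 synthetic stand-in histone sequence
MSGRGKGGKGLGKGGAKRHRKVLRDNIQGITKPAIRRLARRGGVKRISGLIYEETRGVLK
VFLENVIRDAVTYTEHAKRKTVTAMDVVYALKRQGRTLYGFGG
>ceHTAS1 species=celegans family=variant synthetic stand-in histone sequence
MSSTKGGKSKSAKTSQSRSAKAGLQFPVGRVHRLLRKGNYSERVGAGAPVYLAAVLEYLT
AELLELAGNAARDNKKTRIIPRHLQLAIRNDEELNKLLGSVTIAQGGVLPNIQSVLLPKK
SGSSKPSQEL
>ceHTZ1 species=celegans family=variant synthetic stand-in histone sequence
MAGGKAGKDSGKAKTKAVSRSQRAGLQFPVGRIHRHLKSRTTSHGRVGATAAVYSAAILE
YLTAEVLELAGNASKDLKVKRITPRHLQLAIRGDEELDSLIKATIAGGGVIPHIHKSLIG
KKGQQKTV
>mmH2A species=mouse family=H2A synthetic stand-in histone sequence
MSGRGKQGGKARAKAKTRSSRAGLQFPVGRVHRLLRKGNYSERVGAGAPVYLAAVLEYLT
AEILELAGNAARDNKKTRIIPRHLQLAIRNDEELNKLLGRVTIAQGGVLPNIQAVLLPKK
TESHHKAKGK
>mmH2B species=mouse family=H2B synthetic stand-in histone sequence
MPEPAKSAPAPKKGSKKAVTKTQKKDGKKRKRSRKESYSVYVYKVLKQVHPDTGISSKAM
SIMNSFVNDVFERIAGEASRLAHYNKRSTITSREIQTAVRLLLPGELAKHAVSEGTKAVT
KYTSAK
>mmH3 species=mouse family=H3 synthetic stand-in histone sequence
MARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALREIRRYQKSTE
LLIRKLPFQRLVREIAQDFKTDLRFQSSAVMALQEASEAYLVGLFEDTNLCAIHAKRVTI
MPKDIQLARRIRGERA
>mmH4 species=mouse family=H4 synthetic stand-in histone sequence
MSGRGKGGKGLGKGGAKRHRKVLRDNIQGITKPAIRRLARRGGVKRISGLIYEETRGVLK
VFLENVIRDAVTYTEHAKRKTVTAMDVVYALKRQGRTLYGFGG
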