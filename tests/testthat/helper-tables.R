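## Reported mature peptides with printed charge and mean
## hydrophobicity (consensus scale), shared by the physchem and
## acceptance suites.
TAB3 <- data.frame(
  seq = c("FLGALGNALSRVLGK","FIGALVNALTRVLGK","FIGALVHALTGILGK",
    "LVPFIGRTLGGLLARFGK","VPQLCFKFQKVIYCEINRTLPNEA","FSQLFFAWLLRLCRQ",
    "GIVEAWPLR","NNLRHIVAWCKNRNYSLAVCARFKPQ",
    "NLLGFLQGAKDILKECEADNYQGWLCESYKPQ",
    "FLPLVLGKTHSEQAEILSWKSSNVEYHLPKCTTDV","FLPLIAGLWVNCSANNPKMLKLWK",
    "FLPICDKSALRFVGKV","EMPMKKKEETIQKKGMLKWKTIFTSHCWSFE",
    "RGLLDPITGLVGGLLR","FLGFVGQALNALLGKLGK","FLPAIAGILSQIFGK",
    "FFPAFLKVAAKVVPSIICSITKNVET","IVPILLGVVPQLVCAITKKC",
    "IIPLLLGKVVCAITKKC","LVPMFLSKLICFITKKC","GLEVLGKILSGILGK",
    "LLGAALSALSSVIPSVISWFQKG","LANRAARNTSQNVLNAITCTL",
    "ADFLDKLRNFAAKNLQNKASL","EMLRKKEETIQKKGMLKWKNDFYQSLLEF",
    "QKTYNRRPPGWSLYVFHQQISNLELEVI","FVPLLVSKLVCVVTKNVRIWKLELEII",
    "FVPLLVSKLVCVVTKNVRTLET","FLPIVTNLLLRFVG"),
  charge = c(3,3,2,4,2,3,1,6,-1,0,4,3,4,2,3,2,3,3,4,4,2,2,3,3,3,2,3,3,2),
  H = c(0.813,1.213,2.247,1.500,-0.625,2.587,1.133,-1.612,-1.250,
        -0.763,1.363,0.494,-1.835,1.213,1.550,2.540,0.573,1.675,1.271,
        1.918,1.220,1.670,-1.662,-1.595,-1.779,-0.654,1.663,0.455,3.729),
  stringsAsFactors = FALSE)

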