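"species","year","country"
"sp0001",1977,"IL"
"sp0001",1977,"LB"
"sp0001",1978,"CY"
"sp0001",1978,"TR"
"sp0001",1981,"GR"
"sp0001",1981,"LY"
"sp0001",1981,"MT"
"sp0001",1981,"TN"
"sp0001",1982,"IT"
"sp0001",1985,"DZ"
"sp0001",1986,"ES"
"sp0002",1989,"IL"
"sp0002",1989,"LB"
"sp0002",1990,"CY"
"sp0002",1994,"TR"
"sp0002",1996,"GR"
"sp0002",1996,"LY"
"sp0002",1996,"MT"
"sp0002",1996,"TN"
"sp0002",1996,"IT"
"sp0002",1996,"DZ"
"sp0002",1998,"ES"
"sp0003",1964,"IL"
"sp0003",1968,"LB"
"sp0003",1968,"CY"
"sp0003",1970,"TR"
"sp0003",1975,"GR"
"sp0003",1976,"LY"
"sp0003",1976,"MT"
"sp0003",1978,"TN"
"sp0003",1980,"IT"
"sp0003",1980,"DZ"
"sp0003",1980,"ES"
"sp0004",1974,"IL"
"sp0004",1974,"LB"
"sp0004",1974,"CY"
"sp0004",1976,"TR"
"sp0004",1976,"GR"
"sp0004",1977,"LY"
"sp0004",1977,"MT"
"sp0004",1979,"TN"
"sp0004",1985,"IT"
"sp0004",1993,"DZ"
"sp0004",1995,"ES"
"sp0005",1977,"IL"
"sp0005",1978,"LB"
"sp0005",1979,"CY"
"sp0005",1979,"TR"
"sp0005",1979,"GR"
"sp0005",1983,"LY"
"sp0005",1983,"MT"
"sp0005",1987,"TN"
"sp0005",1989,"IT"
"sp0005",1989,"DZ"
"sp0005",1991,"ES"
"sp0006",1985,"IL"
"sp0006",1985,"LB"
"sp0006",1985,"CY"
"sp0006",1985,"TR"
"sp0006",1987,"GR"
"sp0006",1992,"LY"
"sp0006",1994,"MT"
"sp0006",1994,"TN"
"sp0006",1995,"IT"
"sp0006",1995,"DZ"
"sp0006",1996,"ES"
"sp0007",1956,"IL"
"sp0007",1956,"LB"
"sp0007",1956,"CY"
"sp0007",1958,"TR"
"sp0007",1961,"GR"
"sp0007",1965,"LY"
"sp0007",1967,"MT"
"sp0007",1968,"TN"
"sp0007",1968,"IT"
"sp0007",1969,"DZ"
"sp0007",1969,"ES"
"sp0008",1969,"IL"
"sp0008",1969,"LB"
"sp0008",1970,"CY"
"sp0008",1971,"TR"
"sp0008",1971,"GR"
"sp0008",1971,"LY"
"sp0008",1973,"MT"
"sp0008",1973,"TN"
"sp0008",1973,"IT"
"sp0008",1974,"DZ"
"sp0008",1976,"ES"
"sp0009",1986,"IL"
"sp0009",1987,"LB"
"sp0009",1987,"CY"
"sp0009",1989,"TR"
"sp0009",1990,"GR"
"sp0010",1964,"IL"
"sp0010",1964,"LB"
"sp0010",1964,"CY"
"sp0010",1974,"TR"
"sp0010",1974,"GR"
"sp0011",1967,"IL"
"sp0011",1967,"LB"
"sp0011",1967,"CY"
"sp0011",1973,"TR"
"sp0011",1975,"GR"
"sp0012",1969,"IL"
"sp0012",1969,"LB"
"sp0012",1969,"CY"
"sp0012",1970,"TR"
"sp0012",1973,"GR"
"sp0013",1982,"IL"
"sp0013",1984,"LB"
"sp0013",1984,"CY"
"sp0013",1984,"TR"
"sp0013",1984,"GR"
"sp0014",1961,"IL"
"sp0014",1962,"LB"
"sp0014",1962,"CY"
"sp0014",1970,"TR"
"sp0014",1970,"GR"
"sp0015",1972,"IL"
"sp0015",1972,"LB"
"sp0015",1973,"CY"
"sp0015",1974,"TR"
"sp0015",1975,"GR"
"sp0016",1986,"IL"
"sp0016",1991,"LB"
"sp0016",1992,"CY"
"sp0016",1993,"TR"
"sp0016",1996,"GR"
"sp0017",1982,"IL"
"sp0017",1982,"LB"
"sp0018",1970,"IL"
"sp0018",1970,"LB"
"sp0019",1974,"IL"
"sp0019",1976,"LB"
"sp0020",1986,"IL"
"sp0020",1986,"LB"
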