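# Principal-isotope exact masses (Da), AME2020/IUPAC. One row per element:
# symbol, mass number of the most abundant isotope, exact mass of that isotope.
element	mass_number	exact_mass
H	1	1.00782503207
C	12	12.00000000000
N	14	14.00307400480
O	16	15.99491461960
P	31	30.97376163000
S	32	31.97207100000
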