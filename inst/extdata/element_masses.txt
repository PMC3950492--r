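# Pinned atomic-mass constants used for all mass arithmetic in lipidmz.
#
# monoisotopic.*  mass of the most abundant isotope, in Da
#                 source: AME2020 atomic mass evaluation (CODATA-consistent)
# average.*       standard atomic weight, in Da
#                 source: IUPAC CIAAW 2021 abridged standard atomic weights
#                 (conventional value used where CIAAW gives an interval)
# electron_mass   CODATA 2018 electron mass, in Da
#
# Charged adducts are corrected by one electron mass per elementary charge:
# [M+H]+ adds a proton (1.00782503 - 0.00054858 = 1.00727645 Da),
# [M-H]- removes a proton.
version=IUPAC-CIAAW-2021/AME2020, pinned 2026-09
monoisotopic.H=1.00782503224
monoisotopic.C=12.0
monoisotopic.N=14.00307400446
monoisotopic.O=15.99491461960
monoisotopic.P=30.97376199843
monoisotopic.Li=7.01600343666
monoisotopic.Na=22.98976928199
monoisotopic.K=38.96370648661
average.H=1.008
average.C=12.011
average.N=14.007
average.O=15.999
average.P=30.973761998
average.Li=6.94
average.Na=22.98976928
average.K=39.0983
electron_mass=0.000548579909
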