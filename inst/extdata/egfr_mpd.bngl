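# Early EGFR signaling: ligand binding, receptor dimerization,
# transphosphorylation within dimers, dephosphorylation.
# Rate constants are symbolic placeholders; kinetics never affects the
# process diagram.
begin model
begin parameters
  kon 1
  kdp 1
  kdim 1
  kp 1
end parameters
begin molecule types
  EGF(site)
  EGFR(ecd,tmd,Y1~U~P,Y2~U~P)
end molecule types
begin seed species
  EGF(site) 100
  EGFR(ecd,tmd,Y1~U,Y2~U) 100
  EGFR(ecd,tmd,Y1~U,Y2~P) 100
  EGFR(ecd,tmd,Y1~P,Y2~U) 100
  EGFR(ecd,tmd,Y1~P,Y2~P) 100
end seed species
begin reaction rules
  EGF(site) + EGFR(ecd,tmd) -> EGF(site!1).EGFR(ecd!1,tmd) kon
  EGFR(Y1~P) -> EGFR(Y1~U) kdp
  EGFR(Y2~P) -> EGFR(Y2~U) kdp
  EGFR(ecd!+,tmd) + EGFR(ecd!+,tmd) -> EGFR(ecd!+,tmd!1).EGFR(ecd!+,tmd!1) kdim
  EGFR(tmd!1).EGFR(tmd!1,Y1~U) -> EGFR(tmd!1).EGFR(tmd!1,Y1~P) kp
  EGFR(tmd!1).EGFR(tmd!1,Y2~U) -> EGFR(tmd!1).EGFR(tmd!1,Y2~P) kp
end reaction rules
end model
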