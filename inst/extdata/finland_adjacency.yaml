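# Adjacency of the 13 Finnish subpopulation sampling regions.
# Edges approximate geographic neighbourhood; both the southwestern
# (AL, TU, HA, VA, UU, LMO) and northeastern (MI, CF, KU, KY, NC, OU, LA)
# blocks induce connected subgraphs.
nodes: [AL, TU, HA, VA, UU, LMO, MI, CF, KU, KY, NC, OU, LA]
edges:
  - [AL, TU]
  - [TU, UU]
  - [TU, HA]
  - [TU, VA]
  - [UU, HA]
  - [UU, KY]
  - [UU, LMO]
  - [HA, VA]
  - [HA, CF]
  - [HA, LMO]
  - [VA, CF]
  - [VA, OU]
  - [LMO, MI]
  - [LMO, KY]
  - [KY, MI]
  - [MI, KU]
  - [MI, CF]
  - [CF, KU]
  - [CF, OU]
  - [KU, NC]
  - [KU, OU]
  - [NC, OU]
  - [OU, LA]
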