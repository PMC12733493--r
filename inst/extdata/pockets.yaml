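# Pocket catalogue: named residue lists defining binding-site regions.
# Shipped entries: the Sudlow drug-binding sites of human serum albumin
# (site I in subdomain IIA, site II in subdomain IIIA).

sudlow_I:
  residues:
    - {resid: TYR, resno: 150}
    - {resid: LYS, resno: 195}
    - {resid: GLN, resno: 196}
    - {resid: ARG, resno: 197}
    - {resid: LEU, resno: 198}
    - {resid: LYS, resno: 199}
    - {resid: CYS, resno: 200}
    - {resid: ALA, resno: 201}
    - {resid: SER, resno: 202}
    - {resid: LEU, resno: 203}
    - {resid: GLN, resno: 204}
    - {resid: PHE, resno: 211}
    - {resid: TRP, resno: 214}
    - {resid: ALA, resno: 215}
    - {resid: ARG, resno: 218}
    - {resid: LEU, resno: 219}
    - {resid: ARG, resno: 222}
    - {resid: PHE, resno: 223}
    - {resid: LEU, resno: 234}
    - {resid: LEU, resno: 238}
    - {resid: VAL, resno: 241}
    - {resid: HIS, resno: 242}
    - {resid: CYS, resno: 245}
    - {resid: CYS, resno: 246}
    - {resid: HIS, resno: 247}
    - {resid: CYS, resno: 253}
    - {resid: ARG, resno: 257}
    - {resid: LEU, resno: 260}
    - {resid: ALA, resno: 261}
    - {resid: ILE, resno: 264}
    - {resid: ILE, resno: 290}
    - {resid: ALA, resno: 291}
    - {resid: GLU, resno: 292}

sudlow_II:
  residues:
    - {resid: PRO, resno: 384}
    - {resid: LEU, resno: 387}
    - {resid: ILE, resno: 388}
    - {resid: ASN, resno: 391}
    - {resid: CYS, resno: 392}
    - {resid: PHE, resno: 395}
    - {resid: ARG, resno: 410}
    - {resid: TYR, resno: 411}
    - {resid: LYS, resno: 414}
    - {resid: LEU, resno: 430}
    - {resid: VAL, resno: 433}
    - {resid: CYS, resno: 438}
    - {resid: ALA, resno: 449}
    - {resid: GLU, resno: 450}
    - {resid: LEU, resno: 453}
    - {resid: VAL, resno: 455}
    - {resid: ARG, resno: 485}
    - {resid: SER, resno: 489}
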