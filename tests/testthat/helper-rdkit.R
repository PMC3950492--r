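# RDKit (via the system python) as an independent cheminformatics oracle:
# parses generated SMILES and reports the derived molecular formula and the
# number of Z- and E-flagged C=C bonds, in one batched subprocess call.

rdkit_check <- function(smiles) {
  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile(fileext = ".tsv")
  writeLines(smiles, infile)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem.rdMolDescriptors import CalcMolFormula",
    "out = open(sys.argv[2], 'w')",
    "for line in open(sys.argv[1]):",
    "    smi = line.strip()",
    "    m = Chem.MolFromSmiles(smi)",
    "    if m is None:",
    "        out.write('PARSE_FAIL\\t0\\t0\\t0\\n'); continue",
    "    Chem.AssignStereochemistry(m, cleanIt=True, force=True)",
    "    z = sum(1 for b in m.GetBonds() if b.GetStereo()==Chem.BondStereo.STEREOZ)",
    "    e = sum(1 for b in m.GetBonds() if b.GetStereo()==Chem.BondStereo.STEREOE)",
    "    cc = sum(1 for b in m.GetBonds() if b.GetBondType()==Chem.BondType.DOUBLE",
    "             and b.GetBeginAtom().GetSymbol()=='C' and b.GetEndAtom().GetSymbol()=='C')",
    "    f = CalcMolFormula(m).replace('+','').replace('-','')",
    "    out.write(f'{f}\\t{z}\\t{e}\\t{cc}\\n')",
    "out.close()"), script)
  status <- system2("python", c(script, infile, outfile))
  stopifnot(status == 0L)
  res <- utils::read.delim(outfile, header = FALSE,
                           col.names = c("formula", "z", "e", "cc"),
                           stringsAsFactors = FALSE)
  stopifnot(nrow(res) == length(smiles))
  res
}
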