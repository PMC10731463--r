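# User-supplied public sequence/structure data

Some analyses compare against public database entries that this package
does not redistribute. To run them, place the files below in this
directory (an installed copy lives at
`system.file("extdata", "accessions", package = "septG")`; you can also
point the functions at any other directory).

- `<ACCESSION>.fasta` — one full-length protein sequence per file, e.g.
  `P32458.fasta` (ScCdc11), `Q04921.fasta` (ScSpr28), `EJT42412.fasta`,
  `NP_986841.fasta`, `NP_985300.1.fasta`, `EJT41514.1.fasta`, and the
  nematode UNC-61 homolog set (`KAK0406599.1.fasta`, `KAE9549512.1.fasta`,
  `WKX94742.1.fasta`, `CAJ0608469.1.fasta`, `NP_506638.2.fasta`,
  `KAI1730409.1.fasta`, `XP_024506053.1.fasta`, `CDJ88949.1.fasta`,
  `KJH45839.1.fasta`, `VDD93301.1.fasta`, `CAD2194965.1.fasta`,
  `XP_024504518.1.fasta`). Fetch from NCBI Entrez
  (`efetch -db protein -id <ACC> -format fasta`) or UniProt.
- `unc61_species.tsv` — tab-separated table with columns `accession` and
  `organism` for the UNC-61 homolog set, as annotated in the source
  database records.
- `8SGD.pdb` — the Cdc3-Cdc10 GTPase-domain crystal structure, from
  https://files.rcsb.org/download/8SGD.pdb. Chain identities (which chain
  is Cdc3 vs Cdc10) are taken from the entry's own metadata, not guessed.

Nothing in this directory is required for the package's test fixtures,
which are generated synthetically with known ground truth.
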