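# dnasga

Identification of DNA coding sequences as codewords — or near-codewords —
of single-error-correcting BCH codes over the Galois ring GR(4,m) and the
Galois field GF(4^m).

## The problem

Under a *labeling* (a bijection between the nucleotides {A, C, G, T} and
the four symbols of Z4 or GF(4)), a DNA sequence of length n becomes a
vector over a four-letter algebra. For suitable cyclic codes it turns out
that biological coding sequences frequently lie at Hamming distance
exactly 1 from a codeword — they belong to the "cloud" of the code. The
codeword itself, mapped back to nucleotides (the *code-generated
sequence*), differs from the biological sequence at a single position and
proposes an alternative base there. The interest of that proposal is
evolutionary: the suggested substitution is often found at the same
position in distantly related taxa, and the implied codon change is often
synonymous under deviant (noncanonical) genetic codes, e.g. mitochondrial
codes in which TGA is read as Trp, AGA as Ser or ATA as Met.

`dnasga` implements that identification machinery end to end:

* **Algebra** — exact arithmetic in GF(4) = {0, 1, a, b} (b = a + 1,
  arithmetic mod t² + t + 1), in GF(4^m), in Z4[x] and in the Galois ring
  GR(4,m) = Z4[x]/(h(x)); the Graeffe/Hensel lift taking a binary
  primitive polynomial f₂ to the basic irreducible h with h ≡ f₂ (mod 2),
  via h(y) = ±(e(y)² − y·d(y)²) mod 4 where f₂(x) = e(x²) + x·d(x²).
* **Codes** — the built-in registry of 15 presets (field and ring codes of
  length 63, and the (1023, 1013, 3) BCH code over Z4 with generator
  g(x) = x¹⁰ + x⁹ + x⁸ + 3x⁷ + x⁶ + x⁴ + x³ + 3x + 1), encoding,
  syndromes s₁ = r(β), s₂ = r(β²), membership tests, and a computational
  certificate that the minimum Hamming weight is exactly 3.
* **Decoding** — closed-form single-error syndrome decoding (the t = 1
  specialisation of the Berlekamp–Massey algorithm for fields and of the
  Modified Berlekamp–Massey algorithm for Galois rings), plus an
  independent brute-force oracle that tests all 3n single-symbol
  modifications through divisibility by g(x).
* **Pipeline** — labelings A–D, FASTA input, identification verdicts
  (codeword / cloud / unidentified) with 1-based positions, TSV/JSON
  reports, a seeded synthetic fixture generator, and codon annotation
  under the standard and six deviant genetic-code tables.

## Worked example

```r
library(dnasga)

code <- build_code("S02.b")
code
#> BCH code [S02.b] (63, 57, 3) over GR(4,6)
#>   primitive polynomial: x^6+x^4+x^3+x+1
#>   generator polynomial: x^6+2x^5+x^4+x^3+3x+1

lab <- sga_labeling("B")
fx  <- generate_fixtures(code, lab, n_seq = 1, errors = 1, seed = 42)
fx$truth
#>     seq_id planted_position ref alt
#> 1 fix_0001               24   T   G

res <- identify_sequence(fx$sequences[1], code, lab)
res
#> identification of 'fix_0001' against [S02.b] with labeling B: cloud
#>   position 24 (1-based): G -> T

ann <- annotate_codon(res)
ann
#> codon 8: GCG -> GCT (standard: A -> A)
#>   synonymous under: standard, vertebrate-mito, yeast-mito,
#>   mold-protozoan-mito, invertebrate-mito, ciliate-nuclear, cys-reassignment

classify_effect(ann)[c("standard", "vertebrate-mito")]
#>        standard vertebrate-mito
#>        "silent"        "silent"
```

The fixture generator planted a T→G substitution at position 24 of a
random codeword image; `identify_sequence` declares the sequence a cloud
member, recovers the position, and suggests restoring the T. The affected
codon (the 8th, frame offset 0) changes GCG→GCT, which is synonymous
(Ala→Ala) under every shipped table — a silent suggestion.

A thin command-line front end lives in `inst/cli/dnasga.R`:

```sh
Rscript inst/cli/dnasga.R lift "x^6+x^4+x^3+x+1"    # x^6+2x^5+x^4+x^3+3x+1
Rscript inst/cli/dnasga.R codes                      # the 15 presets
Rscript inst/cli/dnasga.R identify --input x.fa --code S02.b --labeling B --out report.tsv
```

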