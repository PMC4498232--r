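---
title: "Methods: BCH codes over Galois rings and fields for DNA sequence identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BCH codes over Galois rings and fields for DNA sequence identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnasga)
```

## The model

A DNA sequence of length $n$ over $\{A,C,G,T\}$ is mapped, through a
bijective *labeling*, to a vector over a four-element symbol alphabet:
$\mathbb{Z}_4 = \{0,1,2,3\}$ for ring codes, $GF(4) = \{0,1,a,b\}$ for
field codes. The vector is read as the coefficient sequence of a
polynomial $r(x)$: position $i$ (1-based, leftmost first) carries the
coefficient of $x^{n-i}$. A cyclic code with generator polynomial $g(x)$
dividing $x^n - 1$ declares $r$ a codeword exactly when $g \mid r$.

The codes used here are single-error-correcting BCH codes, i.e. $g$ has
two consecutive powers $\beta, \beta^2$ of a primitive element among its
roots, which forces minimum Hamming distance $\ge 3$:

* **Field case.** $\beta = \alpha$, the residue of $x$ in
  $GF(4^m) = GF(4)[x]/(p(x))$ for a primitive $p$ of degree $m$ over
  $GF(4)$; $n = 4^m - 1$ and
  $g = \mathrm{minpoly}(\alpha)\cdot\mathrm{minpoly}(\alpha^2)$
  (conjugacy under the Frobenius $x \mapsto x^4$), of degree $2m$.
* **Ring case.** $\beta = \xi$, the Teichmüller unit of
  $GR(4,m) = \mathbb{Z}_4[x]/(h(x))$, where $h$ is the Graeffe/Hensel
  lift of a binary primitive polynomial $f_2$: writing
  $f_2(x) = e(x^2) + x\,d(x^2)$,
  $h(y) = \pm\big(e(y)^2 - y\,d(y)^2\big) \bmod 4$, with the sign
  ($(-1)^{\deg f_2}$) making $h$ monic. Then $h \equiv f_2 \pmod 2$,
  $\xi$ has order $n = 2^m - 1$, and $h$ itself is the generator: its
  roots are the Teichmüller conjugates $\xi, \xi^2, \xi^4, \dots$, so the
  consecutive pair $\xi, \xi^2$ comes for free and $k = n - m$.

Given syndromes $s_1 = r(\beta)$, $s_2 = r(\beta^2)$, a sequence is

* a **codeword** when $s_1 = s_2 = 0$;
* a **cloud** member when subtracting a single error term $e\,x^{\,j}$
  yields a codeword. With $t = 1$ the Berlekamp–Massey (field) and
  Modified Berlekamp–Massey (ring) algorithms collapse to closed form,
  which is how the decoder is implemented (a general error-locator
  iteration would do no additional work at designed distance 3).
  Field: $\beta^{\,j} = s_2/s_1$ and $e = s_1^2/s_2$, accepted only when
  $e \in GF(4)^\times$. Ring, unit branch ($s_1 \notin 2\,GR$): $j$ is the
  difference of the discrete logs of the mod-2 images of $s_1, s_2$ in
  $GF(2^m)$, and $e \in \{1,3\}$ must reproduce both syndromes. Ring,
  zero-divisor branch ($s_1 \in 2\,GR$, $e = 2$): halving $s_1$ gives the
  mod-2 image of $\xi^{\,j}$ directly, and $s_2 = 2\xi^{2j}$ is
  confirmed;
* **unidentified** otherwise (distance $\ge 2$ from every codeword).

Since the code has minimum distance exactly 3 (certified computationally,
below), distance-1 decoding is unambiguous: a cloud sequence has a unique
nearest codeword, whose nucleotide image — the *code-generated sequence* —
differs from the input at exactly the reported position.

## Conventions and numerical choices

* **GF(4) presentation.** $GF(4) = \{0, 1, a, b\}$ with $b = a + 1$,
  arithmetic modulo $t^2+t+1$; integers 0–3 encode $0, 1, a, b$. The
  preset tables use $a, b$ without defining them; this presentation is
  the standard one, and under it every preset's degree-3 primitive
  polynomial has a root of full order 63 and reproduces the preset's
  printed degree-6 generator — verified by the test suite — so the
  alternative assignment ($a \leftrightarrow b$, also of full order) is
  not needed.
* **Element representation.** Field elements are coefficient vectors over
  $GF(4)$ packed 2 bits per coefficient, so addition is XOR;
  multiplication uses precomputed log/antilog tables of $\alpha$. Ring
  elements are length-$m$ coordinate vectors over $\mathbb{Z}_4$; the
  power table of $\xi$ and the log table of the mod-2 image field back
  the decoder. These are internal contracts: all public behaviour is
  representation-independent.
* **Degree convention.** Leftmost symbol = $x^{n-1}$, fixed everywhere.
  Identification verdicts are invariant under cyclic shifts; the
  convention only fixes how error positions are reported, and all
  reported positions are 1-based sequence coordinates (R indexing; the
  biologist-facing convention).
* **Polynomial strings.** Descending terms joined by `+`, `^` exponents,
  implicit coefficient 1 (`x^6+2x^5+x^4+x^3+3x+1`); parsing then printing
  is the identity, and the dialect is used bit-exactly in CLI output.
  The zero polynomial prints as `0` and has degree $-\infty$.
* **Degenerate inputs.** Strict length equality between sequence and code
  is required by default; `pad = "trailing-A"` and `truncate = "tail"`
  exist for exploratory use and warn loudly, since there is no principled
  way to fit a gene of non-code length to $n$.
* **Oracle tie-break.** The brute-force identifier returns the
  lexicographically smallest (position, magnitude) when several
  distance-1 codewords exist, and flags ambiguity. The tie-break is
  arbitrary but fixed; it is unreachable for inputs within the decoding
  radius of a distance-3 code.

## The preset registry

The 15 built-in presets pair a primitive polynomial with a printed
generator, a labeling name and an algebra flag. `build_code()` always
*re-derives* the generator from the primitive polynomial and compares:
a mismatch is recorded as a warning, not an error, keeping the preset
table as ground truth. Two consistency notes:

* One preset (`3.a`) is flagged as a ring code but carries a degree-3
  primitive polynomial over $GF(4)$; its printed generator equals the
  *field* construction from that polynomial, so it is built as a field
  code (with a warning). The mathematics admits no other reading: a ring
  preset needs a binary primitive.
* Two presets (`S02.e`, `S02.f`) share a GI number with different
  polynomials; both are kept as separate presets.

## Minimum-weight certificate

The designed distance guarantees $d \ge 3$; `min_weight_certificate()`
makes the claim exact. Weight 1 is impossible because $e\,\beta^{\,j}$
never vanishes (checked over the full power table). For weight 2, by
cyclicity the support may be rotated to contain degree 0, and all
$9(n-1)$ patterns $e_1 + e_2\beta^{\,j}$ are exhausted against both
syndromes over the precomputed tables — the BCH-bound argument made
computational. A weight-3 codeword is then found by bounded search over
supports $\{0, j, k\}$, solving for the third term by discrete log; the
certificate verifies it by the membership test. For the
(1023, 1013, 3) code this completes in well under a second.

## Labelings

The four named labelings are fixed as A: $(A,C,G,T)\to(0,1,2,3)$,
B: $(0,1,3,2)$, C: $(0,2,1,3)$, D: $(0,2,3,1)$, with the $GF(4)$
counterparts via $2 \leftrightarrow a$, $3 \leftrightarrow b$. The
literature that introduced the labeling names does not pin down the
bijections in a self-contained way, so these defaults are a convention of
this package — chosen to fix $A \to 0$ and enumerate distinct images of
G and T — and any bijection can be supplied via
`sga_labeling(name, mapping = ...)`. Nothing downstream depends on the
choice: the identification machinery is labeling-generic, and planted
substitutions are recovered under every bijection (tested).

## Genetic-code tables

Translation uses the NCBI tables via Biostrings: standard (1),
vertebrate mitochondrial (2), yeast mitochondrial (3), mold/protozoan
mitochondrial (4), invertebrate mitochondrial (5) and ciliate nuclear
(6). The TGA→Cys reassignment is lineage-specific; it is shipped as the
Euplotid nuclear table (NCBI 10) under the name `cys-reassignment`.
`annotate_codon()` computes synonymy, never asserts it: a change is
reported synonymous under exactly the tables where both codons translate
identically. The reading frame defaults to offset 0 (sequence starts
in-frame) and is configurable; alterations falling before the frame
start or in an incomplete trailing codon are marked not translatable.

## The synthetic fixture generator

`generate_fixtures()` draws uniform random length-$k$ messages, encodes
them (non-systematically, $m(x)\,g(x)$ — simplest, since messages are
never transmitted here), maps the codewords to DNA and injects 0, 1 or 2
uniform random substitutions at recorded positions. It emulates exactly
the geometric situation the identifier is specified on — codeword images
and their distance-1/distance-2 neighbours — under a fixed seed, so every
planted change is exactly recoverable and runs are byte-reproducible.

It does **not** emulate real coding sequences: no codon usage, GC
content, ORF structure or phylogenetic signal. Passing tests therefore
demonstrate the correctness of the coding-theoretic machinery (encoding,
membership, decoding, reporting), not the empirical claim that biological
sequences tend to lie in the cloud of these codes — that claim concerns
real genes and is outside what synthetic data can establish.

## Verification design and problem sizes

Every decoder verdict can be cross-checked against
`brute_force_identify()`, which knows nothing of syndromes or discrete
logs: it tests the input and all $3n$ single-symbol modifications for
membership through divisibility by $g$, using the linearity of the
division remainder over a precomputed table of $x^p \bmod g$. Membership
itself is computed by two independent routes (long division and
syndromes) that are cross-checked on every call.

The test suite exercises, among others: exhaustive recovery of all
$63 \times 3$ (position, magnitude) errors for a ring and a field preset
and all $63 \times 3$ (position, alternative-base) substitutions for
every 63-nt preset; 500+ sampled errors in the 1023-symbol code; 1000
planted-substitution fixtures per 63-nt preset; and 1000 mixed random
inputs per preset for decoder/oracle agreement. These sizes make the
full suite run in about two minutes while keeping the exhaustive parts
genuinely exhaustive at $n = 63$ and sampling the $n = 1023$ code.

## Limitations

* Only designed distance 3 (one symbol error) is supported; the general
  Berlekamp–Massey iteration for $t > 1$, burst errors, erasures and
  Lee-metric decoding are out of scope.
* The package identifies sequences against *given* codes; it does not
  search the space of generator polynomials or labelings for one that
  identifies a sequence.
* Codon annotation is positional only: no ORF discovery, no
  selenocysteine/pyrrolysine recoding context.
* Run configuration files are YAML (`read_run_config()`); command-line
  flags override config keys.
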