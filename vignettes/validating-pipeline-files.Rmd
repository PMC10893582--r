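---
title: "Validating pipeline files: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating pipeline files: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqvalid)
```

## The validation model

seqvalid treats file validation as a fixed-order pipeline applied
per file. Three universal checks run for every path regardless of type —
existence (`EXISTS`, `READABLE`, `NONEMPTY`), compression integrity
(`COMPRESSION_OK`) and checksum verification (`CHECKSUM_OK`) — followed by
one format-specific check (`FORMAT_OK`) dispatched from a registry, and,
for indexed containers, an index-companionship check (`INDEX_PRESENT`).
A failure at any stage suppresses all later stages for that file: a report
for a nonexistent path contains exactly one failed `EXISTS` result, and a
file with a broken container never reaches its format validator. This
ordering is an invariant the test suite asserts, not a convention.

Each check yields a `CheckResult` (id, pass/fail, human-readable detail
naming a byte offset, line number or companion file). A file's verdict is
derived, never stored: `PASS` exactly when no failed non-warning check is
present. Warning-severity results exist because some defects should be
surfaced without failing a pipeline — a missing BAM index is the canonical
case — and a `strict` flag promotes them to hard failures.

## Quick versus thorough depth

Validation depth is a single flag with a deliberately simple boundary:

* **quick** — magic bytes agree with the extension's claim, BGZF streams
  end with the 28-byte EOF marker, and text/binary grammars are checked on
  the header plus the first 4 records.
* **thorough** — every gzip member / BGZF block is inflated and its CRC32
  and ISIZE trailer verified (zlib does the arithmetic; the walker tracks
  byte offsets so failures are localised), every record of every grammar is
  checked, every ZIP entry is decompressed and compared against its
  central-directory CRC.

The 4-record sample size in quick mode is a package choice; it is enough to
catch off-by-one framing errors (a FASTQ whose quality lines drifted) while
keeping quick mode O(1) in file size for text formats.

## Compression handling

BGZF is treated as a subtype of gzip: a BAM is a valid gzip stream, so a
name claiming plain gzip accepts BGZF content, while the EOF-marker rule
applies whenever the content (or the claim, as for `.bam`) is BGZF. The
marker is a fixed 28-byte empty block, compared byte-exactly. Thorough BGZF
validation additionally walks the declared `BSIZE` chain and requires the
final block to land exactly on end-of-file. Multi-member gzip files
(concatenated members) are legal and all members are verified — transfer
tools produce such files routinely.

Checksums are computed over the compressed on-disk bytes, not decompressed
content, because that is how sidecars are produced in practice (`md5sum`,
`sha512sum` on the transferred artifact). Sidecar parsing accepts the
coreutils dialect and a bare hex digest; comparison is case-insensitive.
Absent sidecars pass with a note — checksum presence is auto-detected, so
absence cannot be an error. Digesting is streaming (constant memory) via
the `digest` package; the gzip/deflate/CRC primitives are compiled against
system zlib because no installed R package exposes per-member gzip walking
with offsets or the raw-deflate encoder the BGZF and ZIP writers need.

## Format grammars

The per-format rules are codified conservatively from the formats'
de-facto standards, grammar-level only:

* **FASTQ** — strict `+`-separator mode: a separator longer than `+` must
  repeat the identifier. The lenient reading (ignore the separator text)
  misses shuffled-record corruption, which is precisely the class of defect
  a pipeline validator exists to catch. Empty sequence lines are rejected;
  CRLF endings are tolerated; the final newline is optional.
* **SAM/BAM** — the operational meaning of "contains sequence data" is:
  correct magic bytes and at least one decodable record with a non-empty
  read name. The binary reference directory must agree with the text
  header's `@SQ` count, but only when the text header declares any `@SQ`
  lines — a BAM with a minimal text header and binary-only references is
  legal.
* **CRAM** — container-level only: magic, plausible version (major 1–3),
  and the byte-exact 38-byte v3 EOF container (verified in the test suite
  against the bytes htslib writes). Parsing CRAM codecs would be out of
  proportion to a truncation/identity check, so records are not decoded.
* **VCF** — grammar only, no semantics: `ALT != REF` and
  contig-declared-in-header are deliberately not enforced. A header-only
  VCF passes with a note by default (`strict` flips it); unusual version
  strings note rather than fail. Version 4.x is the tested dialect.
* **ZIP** — EOCD located in the trailing 65 KiB + 22 bytes (last
  occurrence wins, since comments can embed the signature); entry count
  must match the enumerable central directory. ZIP64 is accepted
  structurally in quick mode but flagged unsupported for thorough CRC
  walking; encrypted entries fail thorough validation explicitly.

Unknown extensions get the universal checks only and a pass-with-note
`FORMAT_OK` — arbitrary files still deserve existence and checksum
verification. There is deliberately no content-based format guessing: a
`.xyz` file that happens to look like FASTQ stays `UNKNOWN`.

## The registry

Dispatch is driven by two runtime-editable mappings: extension → format
(longest suffix wins, case-insensitive) and format → validator. Supporting
a new type is two calls:

```{r registry}
registerFileFormat(".qcx", "QCX")
registerValidator("QCX", function(path, category, thorough, strict) {
    ok <- identical(readLines(path, n = 1L, warn = FALSE), "#QCX")
    list(CheckResult("FORMAT_OK", ok, if (ok) "" else "missing #QCX header"))
})
p <- file.path(tempdir(), "report.qcx")
writeLines(c("#QCX", "metric\t1"), p)
verdict(validateFile(p))
unregisterFileFormat(".qcx"); unregisterValidator("QCX")
```

Removing a registry entry downgrades its files to `UNKNOWN` with no other
code changes — the registry is the single dispatch authority.

## Parallelism

Multi-file runs fork one worker per file (`parallel::mclapply`) at the
file level; reports are collected in input order, so a run with any thread
count is field-identical to a serial run — asserted by serialising both to
JSON and comparing strings. Intra-file parallel validation (splitting one
indexed file across threads) is out of scope. Exit codes are the
workflow-engine contract: 0 all pass, 1 any fail, 2 usage error.

## The fixture forge

Tests and acceptance measurements run entirely on synthetic files from
`makeFixture()`. A `FixtureSpec` (format, seed, record count, corruption
operator, compression) maps to byte-identical output: writers use fixed
gzip header fields (zero mtime, unknown-OS byte) and a fixed compression
level, and all content is drawn from a seeded RNG whose state is restored
afterwards. Record content is biologically arbitrary — random IUPAC
strings, uniform qualities in the Sanger range, two fixed reference
sequences (chr1:1000, chr2:800), read counts defaulting to a handful per
file. Structural validity is the goal; realism (coverage profiles, quality
decay, real genomes) is a non-goal, so passing tests demonstrate that the
validators enforce their grammars, not that real-world files never exhibit
defect classes outside the operator library.

Each corruption operator injects exactly one defect after generating a
valid file, and declares the check it targets (`corruptionTarget()`); the
soundness/completeness matrix asserts that valid fixtures pass thorough
validation and corrupted ones fail with exactly the declared check, over
every applicable (format, operator) pair and five seeds. One defect per
fixture isolates which check catches what. Three operator-design points:

* `BYTE_FLIP` is restricted to compressed containers and ZIP entry data,
  where a one-byte change is guaranteed detectable (CRC mismatch or
  inflate failure). A flip inside plain text can land on a position where
  the mutated byte is still grammatical, which would make "always fails"
  unprovable. Checksum sensitivity over arbitrary positions is measured
  separately: flip any single byte of any fixture and `verifyChecksums()`
  must fail (100 randomized trials).
* `STALE_CHECKSUM` writes the sidecar first, then regenerates the file
  with different valid content (a fixed seed offset), so exactly
  `CHECKSUM_OK` fails.
* `TRUNCATE_TAIL` on a BGZF stream shifts its cut by one byte if it would
  land exactly on a block boundary — a boundary cut leaves a valid gzip
  stream missing only its EOF marker, which blurs which check the
  operator targets.

`ZERO_READS` applies to SAM/BAM only: a header-only VCF passes-with-note
by design, and a zero-record FASTQ is an empty file, caught earlier by
`NONEMPTY`.

## Numerical and degenerate-input choices

Little-endian integers in BAM/ZIP are read into doubles (exact for the
uint32 range, which R integers cannot hold). `POS` accepts [0, 2^31 − 1],
`FLAG` [0, 65535], `MAPQ` [0, 255]. Zero-length files classify as `EMPTY`
before any magic sniffing; directories fail `READABLE`; broken symlinks
count as nonexistent (symlinks are followed, matching what downstream
tools experience). Problem sizes in the tests — fixtures of 1–200 records,
a 40-file parallel set, ≥50 fixtures per oracle comparison, 5 seeds per
matrix cell — were chosen to exercise every branch at sub-minute runtime;
all quantities are rates over those counts and are reported with their
`n` by `scripts/acceptance.R`.

## Oracles

The implementation never delegates to external tools, but the test suite
cross-checks it against independent ones: thorough gzip verdicts against
Python's `gzip` module reading streams to completion, BAM record walking
against `Rsamtools` iteration counts, ZIP verdicts against `unzip -t`, the
BGZF EOF and CRAM EOF constants against bytes written by htslib-family
tools, and digests against published md5/sha512 test vectors and
`tools::md5sum`.

## Known limitations

Quality-encoding detection (phred+33 vs +64), read-pair consistency across
FASTQ files, SAM tag validation, sort-order and reference-MD5 checks, VCF
INFO/FORMAT type checking against header declarations, CRAM block/codec
parsing, ZIP64 thorough walking and nested archives are all out of scope.
Validation is evidence of structural integrity, not of scientific
correctness of the content.
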