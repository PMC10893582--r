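# seqvalid

Validation and integrity checking of bioinformatics file formats.

## The problem

Sequencing pipelines orchestrated with Nextflow- or Snakemake-style engines
move large files between many tools, and they fail late and expensively when
an input is wrong: a path that does not exist, a BGZF stream truncated by an
interrupted transfer, a checksum sidecar that no longer matches, a BAM whose
header was mangled. seqvalid is a library plus command-line tool that checks
files *before* compute is spent on them, and verifies outputs before they
propagate downstream.

Every file receives three universal checks, in order:

1. **Existence** — the path exists, is readable, and is non-empty
   (`EXISTS`, `READABLE`, `NONEMPTY`).
2. **Compression integrity** (`COMPRESSION_OK`) — the magic bytes agree
   with what the extension claims; for BGZF (the blocked-gzip container
   underlying BAM and compressed VCF) the 28-byte EOF marker must terminate
   the file; in *thorough* mode every gzip member / BGZF block is inflated
   and its CRC32 and ISIZE trailer verified, with failures reported at the
   byte offset of the bad block.
3. **Checksum verification** (`CHECKSUM_OK`) — `<file>.md5` and
   `<file>.sha512` sidecars (coreutils dialect) are auto-detected, the
   digest recomputed from the on-disk bytes and compared; absence of
   sidecars is a pass-with-note, a mismatch is a failure naming both
   digests.

A format-specific validator is then dispatched from an extensible registry
keyed on file extension (`FORMAT_OK`, plus `INDEX_PRESENT` for indexed
containers):

| format | checks |
|---|---|
| FASTQ | 4-line record grammar: `@`-header, IUPAC sequence, `+`-separator repetition, quality length and ASCII range; line count a multiple of 4 |
| SAM | header record types and ordering, `@HD`/`@SQ` tag rules, ≥11 fields per alignment with `FLAG`/`POS`/`MAPQ` ranges, `SEQ`/`QUAL` length match, `RNAME` declared, ≥1 read |
| BAM | `BAM\x01` magic in the inflated stream, SAM header text rules, binary reference directory consistent with `@SQ` count, every record's `block_size` chain landing exactly on end-of-data |
| CRAM | `CRAM` magic, plausible version, byte-exact 38-byte v3 EOF container |
| VCF | `##fileformat` declaration, meta-line syntax, `#CHROM` column header, per-record field grammar (`POS`, `REF`, `ALT` alleles, `QUAL`, `INFO`, `FORMAT`/sample consistency) |
| ZIP | end-of-central-directory record locatable, central directory enumerable, per-entry CRC32 in thorough mode |

Quick mode checks magic bytes, EOF markers and the first 4 records; thorough
mode verifies every block and record. Registering a new format at runtime
takes exactly two calls (`registerFileFormat()`, `registerValidator()`) and
nothing else.

The package also ships a deterministic fixture forge (`makeFixture()`):
seeded generators for valid files in every supported format and a library of
named corruption operators (`TRUNCATE_TAIL`, `BYTE_FLIP`, `BAD_MAGIC`,
`STRIP_EOF_BLOCK`, `STALE_CHECKSUM`, ...), each injecting exactly one defect
with a declared target check — the package's own test and acceptance
surface.

## Worked example

```r
library(seqvalid)
d <- file.path(tempdir(), "demo"); dir.create(d)

good  <- makeFixture(fixtureSpec("BAM", seed = 7, nRecords = 10), d)
stale <- makeFixture(fixtureSpec("VCF", seed = 3, nRecords = 25,
                                 corruption = "STALE_CHECKSUM"), d)
trunc <- makeFixture(fixtureSpec("FASTQ", seed = 5, nRecords = 50,
                                 corruption = "TRUNCATE_TAIL",
                                 compress = TRUE), d)

summary <- validatePaths(c(good, stale, trunc), threads = 2, thorough = TRUE)
cat(formatReport(summary, "text"))
#> PASS  /tmp/.../demo/bam_s7_n10_none.bam  BAM
#> FAIL  /tmp/.../demo/vcf_s3_n25_stale_checksum.vcf  CHECKSUM_OK: sha512 mismatch: sidecar .../vcf_s3_n25_stale_checksum.vcf.sha512 has 05485ac0..., file digests to 62c1573d...
#> FAIL  /tmp/.../demo/fastq_s5_n50_truncate_tail.fastq.gz  COMPRESSION_OK: truncated stream at byte offset 2714
#> passed 1 of 3
exitCode(summary)
#> [1] 1
```

The BAM passes all six checks (its BGZF blocks inflate with matching CRCs,
the binary header agrees with its `@SQ` lines, all 10 records decode, and
its `.bai` companion is present). The VCF fails `CHECKSUM_OK` because its
sha512 sidecar describes an earlier version of the file — the report prints
both digests. The gzipped FASTQ fails `COMPRESSION_OK` at the byte offset
where the truncated stream ends, and no later check is attempted: a failure
at any stage suppresses the rest of that file's pipeline. The exit code (0
all passed / 1 any failure / 2 usage error) is what a workflow engine
branches on.

The same run from a shell:

```sh
exec/seqvalid validate demo/*.bam demo/*.vcf demo/*.fastq.gz --thorough -t 2
exec/seqvalid generate-checksum reads.bam --type sha512
```

## Package layout

- `R/` — S4 classes (`FileCategory`, `CheckResult`, `FileReport`,
  `RunSummary`, `FixtureSpec`), the validator registry, the universal
  checks, per-format validators, the runner, the CLI and the fixture forge.
- `src/` — Rcpp/zlib primitives: member-by-member gzip walking with CRC
  verification and byte offsets, raw deflate/inflate, CRC32.
- `exec/seqvalid` — the command-line entry point.
- `vignettes/validating-pipeline-files.Rmd` — the methods vignette: design
  decisions, validation grammars, what the fixture generator does and does
  not emulate.
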