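# Look up the canonical enumerated assignment matching a value-map string,
# so tests never need to construct the internal assignment class by hand.
find_assignment <- function(position, string) {
  target <- format_assignment(parse_assignment(string))
  for (a in enumerate_assignments(position)) {
    if (identical(format_assignment(a$values), target)) return(a)
  }
  stop("no enumerated assignment matches ", string)
}

# Build a property_scale from a named value vector via the public TSV
# interchange format.
make_scale <- function(values, name = "custom") {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write.table(data.frame(aa = names(values), value = unname(values)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  read_property_scale(path, name = name, source = "test fixture")
}

# Write a small FASTA from named sequences and return the path.
local_fasta <- function(seqs, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".ffn", .local_envir = env)
  df <- data.frame(id = names(seqs), cds = unname(seqs),
                   stringsAsFactors = FALSE)
  write_fasta(df, path)
  path
}
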