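# Shared fixtures; the synthetic reference is deterministic and cached by
# the package, so repeated calls are cheap.

test_ref <- function() synthetic_reference()
test_tree <- function() mini_haplo_tree()

# Apply a set of edits to a sequence string (positions refer to the
# original coordinates; edits applied right-to-left).
mutate_seq <- function(seq, edits) {
  edits <- edits[order(-vapply(edits, `[[`, numeric(1), "pos"))]
  for (e in edits) {
    if (e$op == "sub") {
      substr(seq, e$pos, e$pos) <- e$base
    } else if (e$op == "del") {
      seq <- paste0(substr(seq, 1, e$pos - 1),
                    substr(seq, e$pos + e$len, nchar(seq)))
    } else {
      seq <- paste0(substr(seq, 1, e$pos), e$seq,
                    substr(seq, e$pos + 1, nchar(seq)))
    }
  }
  seq
}

other_bases <- function(b) setdiff(c("A", "C", "G", "T"), b)

ref_base <- function(ref, pos) substr(ref$seq, pos, pos)

feature_by_name <- function(ref, name) {
  ref$features[ref$features$name == name, ]
}
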