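#!/usr/bin/env Rscript
# Genome organization of the H. quoyi mitogenome from its published
# annotation table: feature lengths, overlaps, intergenic spacers and
# strand distribution. Writes results/architecture_*.tsv.

library(mitochar)

dir.create("results", showWarnings = FALSE)

ft <- hquoyi_feature_table()
rep <- architecture_report(ft)
print(rep)

lens <- feature_lengths(ft)
message(sprintf("Genome %d bp; 13 PCGs total %d bp (shortest %s %d bp, longest %s %d bp)",
                rep$genome_length, rep$pcg_total_length,
                names(which.min(lens[ft$features$name[ft$features$class == "PCG"]])),
                min(lens[ft$features$name[ft$features$class == "PCG"]]),
                names(which.max(lens[ft$features$name[ft$features$class == "PCG"]])),
                max(lens[ft$features$name[ft$features$class == "PCG"]])))
message(sprintf("rRNAs: 12S %d bp, 16S %d bp; OL %d bp; CR %d bp",
                lens[["rrnS"]], lens[["rrnL"]], lens[["OL"]], lens[["CR"]]))

g_feat <- adjacent_gaps(ft, ol_as_feature = TRUE)
g_noc <- adjacent_gaps(ft, ol_as_feature = FALSE)
message(sprintf("Overlaps: %d locations, %d bp total (largest %s-%s, %d bp)",
                nrow(g_feat$overlaps), sum(g_feat$overlaps$bp),
                g_feat$overlaps$upstream[which.max(g_feat$overlaps$bp)],
                g_feat$overlaps$downstream[which.max(g_feat$overlaps$bp)],
                max(g_feat$overlaps$bp)))
message(sprintf("Spacers (OL excluded): %d locations, %d bp; longest %s-%s = %d bp (hosts the OL)",
                nrow(g_noc$spacers), sum(g_noc$spacers$bp),
                g_noc$spacers$upstream[which.max(g_noc$spacers$bp)],
                g_noc$spacers$downstream[which.max(g_noc$spacers$bp)],
                max(g_noc$spacers$bp)))

write.table(data.frame(feature = names(lens), length_bp = lens),
            "results/architecture_lengths.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(g_feat$overlaps, "results/architecture_overlaps.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(g_noc$spacers, "results/architecture_spacers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(strand_distribution(ft), "results/architecture_strands.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("written: results/architecture_*.tsv")
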