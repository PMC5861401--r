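#!/usr/bin/env python
"""Independent reference evaluator for fully judged runs.

Reads a TREC run file and a 4-column qrels file (topic 0 doc grade, grades
0/1/2) and prints a JSON object with per-topic and mean NDCG@10 (linear
gains, discount 1/log2(rank+1), ideal from the full qrels), P@10 with and
without partial relevance, and average precision (relevant = grade >= 1).
Shares no code with the R implementation; used as a cross-check oracle.
"""
import json
import math
import sys
from collections import defaultdict


def read_run(path):
    runs = defaultdict(list)
    with open(path) as fh:
        for line in fh:
            parts = line.split()
            if not parts:
                continue
            topic, _, doc, rank, score, _tag = parts[:6]
            runs[topic].append((int(rank), doc))
    return {t: [d for _, d in sorted(v)] for t, v in runs.items()}


def read_qrels(path):
    qr = defaultdict(dict)
    with open(path) as fh:
        for line in fh:
            parts = line.split()
            if not parts:
                continue
            topic, _, doc, grade = parts[:4]
            qr[topic][doc] = int(grade)
    return qr


def dcg(gains):
    return sum(g / math.log2(i + 2) for i, g in enumerate(gains))


def evaluate(run, qrels):
    out = {"ndcg10": {}, "p10plus": {}, "p10minus": {}, "ap": {}}
    for topic, docs in sorted(run.items()):
        judged = qrels.get(topic)
        if judged is None:
            continue
        grades = [judged.get(d, 0) for d in docs]
        top = grades[:10]
        ideal = sorted((g for g in judged.values() if g > 0), reverse=True)[:10]
        idcg = dcg(ideal)
        out["ndcg10"][topic] = dcg(top) / idcg if idcg > 0 else 0.0
        out["p10plus"][topic] = sum(1 for g in top if g >= 1) / 10.0
        out["p10minus"][topic] = sum(1 for g in top if g == 2) / 10.0
        R = sum(1 for g in judged.values() if g >= 1)
        hits = 0
        ap = 0.0
        for k, g in enumerate(grades, start=1):
            if g >= 1:
                hits += 1
                ap += hits / k
        out["ap"][topic] = ap / R if R else 0.0
    for m in list(out):
        vals = out[m]
        out[m + "_mean"] = sum(vals.values()) / len(vals) if vals else 0.0
    return out


if __name__ == "__main__":
    run_path, qrels_path = sys.argv[1], sys.argv[2]
    print(json.dumps(evaluate(read_run(run_path), read_qrels(qrels_path))))
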