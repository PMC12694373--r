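"""Independent COCO-style AP reference evaluator.

Reads a JSON file {"dets": [...], "gts": [...], "thresholds": [...]}
where each det is [image_id, category_id, score, x_min, y_min, x_max,
y_max] and each gt is [image_id, category_id, x_min, y_min, x_max,
y_max], and prints a JSON object with per-threshold mAP. Written as a
stand-alone numpy implementation (greedy confidence-ordered matching,
one ground truth per true positive, 101-point interpolation) so the R
evaluator can be cross-checked against it.
"""
import json
import sys

import numpy as np


def iou(box, boxes):
    if len(boxes) == 0:
        return np.zeros(0)
    ix = np.maximum(
        0, np.minimum(box[2], boxes[:, 2]) - np.maximum(box[0], boxes[:, 0]))
    iy = np.maximum(
        0, np.minimum(box[3], boxes[:, 3]) - np.maximum(box[1], boxes[:, 1]))
    inter = ix * iy
    a = max(box[2] - box[0], 0) * max(box[3] - box[1], 0)
    b = np.maximum(boxes[:, 2] - boxes[:, 0], 0) * np.maximum(
        boxes[:, 3] - boxes[:, 1], 0)
    union = a + b - inter
    out = np.zeros_like(union, dtype=float)
    np.divide(inter, union, out=out, where=union > 0)
    return out


def ap_class(dets, gts, thr):
    npos = len(gts)
    if npos == 0:
        return None
    if len(dets) == 0:
        return 0.0
    order = np.argsort([-d[2] for d in dets], kind="stable")
    matched = {}
    tp = np.zeros(len(dets))
    for rank, di in enumerate(order):
        img, _, _, *box = dets[di]
        g = [(j, gg) for j, gg in enumerate(gts) if gg[0] == img]
        if not g:
            continue
        boxes = np.array([gg[2:] for _, gg in g], dtype=float)
        ious = iou(np.array(box, dtype=float), boxes)
        taken = matched.setdefault(img, set())
        for j in np.argsort(-ious, kind="stable"):
            if ious[j] >= thr and g[j][0] not in taken:
                tp[rank] = 1
                taken.add(g[j][0])
                break
            if ious[j] < thr:
                break
    tpc = np.cumsum(tp)
    fpc = np.cumsum(1 - tp)
    recall = tpc / npos
    precision = tpc / (tpc + fpc)
    env = np.maximum.accumulate(precision[::-1])[::-1]
    grid = np.linspace(0, 1, 101)
    idx = np.searchsorted(recall, grid, side="left")
    p = np.where(idx < len(env), env[np.minimum(idx, len(env) - 1)], 0.0)
    return float(p.mean())


def main(path):
    with open(path) as fh:
        data = json.load(fh)
    dets = data["dets"]
    gts = data["gts"]
    thresholds = data["thresholds"]
    classes = sorted({g[1] for g in gts})
    result = {}
    maps = []
    for thr in thresholds:
        aps = []
        for c in classes:
            ap = ap_class([d for d in dets if d[1] == c],
                          [g for g in gts if g[1] == c], thr)
            if ap is not None:
                aps.append(ap)
        maps.append(float(np.mean(aps)))
    result["map_per_threshold"] = maps
    result["map"] = float(np.mean(maps))
    json.dump(result, sys.stdout)


if __name__ == "__main__":
    main(sys.argv[1])
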