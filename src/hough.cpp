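#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Circular Hough accumulator + peak scan.
//
// Each mask boundary pixel p votes for every candidate centre c = p - o,
// o ranging over the rasterized perimeter offsets of each search radius
// (computed in R from the shared disk definition).  Votes are normalized
// by the perimeter pixel count of the radius, so a full rim scores 1
// regardless of r.  Peaks are accumulator cells at or above
// vote_threshold that are >= all in-bounds neighbours in the 3x3x3
// (cy, cx, r) neighbourhood; plateau ties are all kept and resolved by
// the deterministic non-maximum suppression on the R side.
//
// Coordinates in and out are 0-based (row, col).

// [[Rcpp::export]]
NumericMatrix hough_peaks_cpp(IntegerVector by, IntegerVector bx,
                              int height, int width, IntegerVector radii,
                              List off_dy, List off_dx,
                              double vote_threshold) {
    const int nR = radii.size();
    const int npix = height * width;
    const int nb = by.size();

    std::vector< std::vector<double> > score(nR);
    for (int ri = 0; ri < nR; ++ri) {
        score[ri].assign(npix, 0.0);
        IntegerVector dy = off_dy[ri];
        IntegerVector dx = off_dx[ri];
        const int m = dy.size();
        std::vector<double> &A = score[ri];
        for (int i = 0; i < nb; ++i) {
            const int y0 = by[i], x0 = bx[i];
            for (int j = 0; j < m; ++j) {
                const int cy = y0 - dy[j];
                const int cx = x0 - dx[j];
                if (cy >= 0 && cy < height && cx >= 0 && cx < width)
                    A[cy * width + cx] += 1.0;
            }
        }
        const double norm = (double) m;
        for (int k = 0; k < npix; ++k) A[k] /= norm;
    }

    std::vector<double> out;
    for (int ri = 0; ri < nR; ++ri) {
        const std::vector<double> &A = score[ri];
        for (int cy = 0; cy < height; ++cy) {
            for (int cx = 0; cx < width; ++cx) {
                const double s = A[cy * width + cx];
                if (s < vote_threshold) continue;
                bool ismax = true;
                for (int dr = -1; dr <= 1 && ismax; ++dr) {
                    const int rj = ri + dr;
                    if (rj < 0 || rj >= nR) continue;
                    const std::vector<double> &B = score[rj];
                    for (int ddy = -1; ddy <= 1 && ismax; ++ddy) {
                        const int yy = cy + ddy;
                        if (yy < 0 || yy >= height) continue;
                        for (int ddx = -1; ddx <= 1; ++ddx) {
                            const int xx = cx + ddx;
                            if (xx < 0 || xx >= width) continue;
                            if (B[yy * width + xx] > s) { ismax = false; break; }
                        }
                    }
                }
                if (ismax) {
                    out.push_back(cy);
                    out.push_back(cx);
                    out.push_back(radii[ri]);
                    out.push_back(s);
                }
            }
        }
    }

    const int ncand = out.size() / 4;
    NumericMatrix res(ncand, 4);
    for (int i = 0; i < ncand; ++i)
        for (int j = 0; j < 4; ++j) res(i, j) = out[4 * i + j];
    colnames(res) = CharacterVector::create("cy", "cx", "r", "score");
    return res;
}
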