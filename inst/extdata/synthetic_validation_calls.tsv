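# mitoscreen-table v1 validationcalls
target	sirna	rawMnc	manualScore
L001	L001_si1	0.69999999999999996	1
L001	L001_si2	0.75	1
L001	L001_si3	0.94999999999999996	1
L001	L001_si4	1	1
L001	L001_si5	1	1
L002	L002_si1	0.69999999999999996	1
L002	L002_si2	0.75	1
L002	L002_si3	0.94999999999999996	1
L002	L002_si4	1	1
L002	L002_si5	1	1
L003	L003_si1	0.69999999999999996	1
L003	L003_si2	0.75	1
L003	L003_si3	0.94999999999999996	1
L003	L003_si4	1	1
L003	L003_si5	1	1
L004	L004_si1	0.69999999999999996	1
L004	L004_si2	0.75	1
L004	L004_si3	0.94999999999999996	1
L004	L004_si4	1	1
L004	L004_si5	1	1
L005	L005_si1	0.69999999999999996	1
L005	L005_si2	0.75	1
L005	L005_si3	0.94999999999999996	1
L005	L005_si4	1	1
L005	L005_si5	1	1
L006	L006_si1	0.69999999999999996	1
L006	L006_si2	0.75	1
L006	L006_si3	0.94999999999999996	1
L006	L006_si4	1	1
L006	L006_si5	1	1
L007	L007_si1	0.69999999999999996	1
L007	L007_si2	0.75	1
L007	L007_si3	0.94999999999999996	1
L007	L007_si4	1	1
L007	L007_si5	1	1
L008	L008_si1	0.69999999999999996	1
L008	L008_si2	0.75	1
L008	L008_si3	0.94999999999999996	1
L008	L008_si4	1	1
L008	L008_si5	1	1
L009	L009_si1	0.94999999999999996	1
L009	L009_si2	0.94999999999999996	1
L009	L009_si3	0.94999999999999996	1
L009	L009_si4	1	1
L009	L009_si5	0.5	1
L010	L010_si1	0.94999999999999996	1
L010	L010_si2	0.94999999999999996	1
L010	L010_si3	0.94999999999999996	1
L010	L010_si4	1	1
L010	L010_si5	1	1
L011	L011_si1	0.94999999999999996	1
L011	L011_si2	0.94999999999999996	1
L011	L011_si3	0.94999999999999996	1
L011	L011_si4	1	1
L011	L011_si5	1	1
L012	L012_si1	0.94999999999999996	1
L012	L012_si2	0.94999999999999996	1
L012	L012_si3	0.94999999999999996	1
L012	L012_si4	1	1
L012	L012_si5	1	1
L013	L013_si1	0.94999999999999996	1
L013	L013_si2	0.94999999999999996	1
L013	L013_si3	0.94999999999999996	1
L013	L013_si4	1	1
L013	L013_si5	1	1
L014	L014_si1	0.94999999999999996	1
L014	L014_si2	0.94999999999999996	1
L014	L014_si3	0.94999999999999996	1
L014	L014_si4	1	1
L014	L014_si5	1	1
L015	L015_si1	0.69999999999999996	1
L015	L015_si2	0.75	1
L015	L015_si3	0.94999999999999996	1
L015	L015_si4	1	1
L015	L015_si5	1	1
L016	L016_si1	0.69999999999999996	1
L016	L016_si2	0.75	1
L016	L016_si3	0.94999999999999996	1
L016	L016_si4	1	1
L016	L016_si5	1	1
L017	L017_si1	0.69999999999999996	1
L017	L017_si2	0.75	1
L017	L017_si3	0.94999999999999996	1
L017	L017_si4	1	1
L017	L017_si5	1	1
L018	L018_si1	0.69999999999999996	1
L018	L018_si2	0.75	1
L018	L018_si3	0.94999999999999996	1
L018	L018_si4	1	1
L018	L018_si5	1	1
L019	L019_si1	0.69999999999999996	1
L019	L019_si2	0.75	1
L019	L019_si3	0.94999999999999996	1
L019	L019_si4	1	1
L019	L019_si5	1	1
L020	L020_si1	0.69999999999999996	1
L020	L020_si2	0.75	1
L020	L020_si3	0.94999999999999996	1
L020	L020_si4	1	1
L020	L020_si5	1	1
L021	L021_si1	0.94999999999999996	1
L021	L021_si2	0.94999999999999996	1
L021	L021_si3	0.94999999999999996	1
L021	L021_si4	1	1
L021	L021_si5	0.5	1
L022	L022_si1	0.94999999999999996	1
L022	L022_si2	0.94999999999999996	1
L022	L022_si3	0.94999999999999996	1
L022	L022_si4	1	1
L022	L022_si5	1	1
L023	L023_si1	0.94999999999999996	1
L023	L023_si2	0.94999999999999996	1
L023	L023_si3	0.94999999999999996	1
L023	L023_si4	1	1
L023	L023_si5	1	1
L024	L024_si1	0.94999999999999996	1
L024	L024_si2	0.94999999999999996	1
L024	L024_si3	0.94999999999999996	1
L024	L024_si4	1	1
L024	L024_si5	1	1
L025	L025_si1	0.94999999999999996	1
L025	L025_si2	0.94999999999999996	1
L025	L025_si3	0.94999999999999996	1
L025	L025_si4	1	1
L025	L025_si5	1	1
L026	L026_si1	0.94999999999999996	1
L026	L026_si2	0.94999999999999996	1
L026	L026_si3	0.94999999999999996	1
L026	L026_si4	1	1
L026	L026_si5	1	1
L027	L027_si1	0.94999999999999996	1
L027	L027_si2	0.94999999999999996	1
L027	L027_si3	0.94999999999999996	1
L027	L027_si4	1	1
L027	L027_si5	1	1
L028	L028_si1	0.69999999999999996	1
L028	L028_si2	0.75	1
L028	L028_si3	0.94999999999999996	1
L028	L028_si4	1	1
L028	L028_si5	1	1
L029	L029_si1	0.69999999999999996	1
L029	L029_si2	0.75	1
L029	L029_si3	0.94999999999999996	1
L029	L029_si4	1	1
L029	L029_si5	1	1
L030	L030_si1	0.69999999999999996	1
L030	L030_si2	0.75	1
L030	L030_si3	0.94999999999999996	1
L030	L030_si4	1	1
L030	L030_si5	1	1
L031	L031_si1	0.69999999999999996	1
L031	L031_si2	0.75	1
L031	L031_si3	0.94999999999999996	1
L031	L031_si4	1	1
L031	L031_si5	1	1
L032	L032_si1	0.69999999999999996	1
L032	L032_si2	0.75	1
L032	L032_si3	0.94999999999999996	1
L032	L032_si4	1	1
L032	L032_si5	1	1
L033	L033_si1	0.69999999999999996	1
L033	L033_si2	0.75	1
L033	L033_si3	0.94999999999999996	1
L033	L033_si4	1	1
L033	L033_si5	1	1
L034	L034_si1	0.69999999999999996	1
L034	L034_si2	0.75	1
L034	L034_si3	0.94999999999999996	1
L034	L034_si4	1	1
L034	L034_si5	1	1
L035	L035_si1	0.69999999999999996	1
L035	L035_si2	0.75	1
L035	L035_si3	0.94999999999999996	1
L035	L035_si4	1	1
L035	L035_si5	1	1
L036	L036_si1	0.69999999999999996	1
L036	L036_si2	0.75	1
L036	L036_si3	0.94999999999999996	1
L036	L036_si4	1	1
L036	L036_si5	1	1
L037	L037_si1	0.69999999999999996	1
L037	L037_si2	0.75	1
L037	L037_si3	0.94999999999999996	1
L037	L037_si4	1	1
L037	L037_si5	1	1
L038	L038_si1	0.69999999999999996	1
L038	L038_si2	0.75	1
L038	L038_si3	0.94999999999999996	1
L038	L038_si4	1	1
L038	L038_si5	1	1
L039	L039_si1	0.69999999999999996	1
L039	L039_si2	0.75	1
L039	L039_si3	0.94999999999999996	1
L039	L039_si4	1	1
L039	L039_si5	1	1
L040	L040_si1	0.94999999999999996	1
L040	L040_si2	0.94999999999999996	1
L040	L040_si3	0.94999999999999996	1
L040	L040_si4	1	1
L040	L040_si5	0.5	1
L041	L041_si1	0.94999999999999996	1
L041	L041_si2	0.94999999999999996	1
L041	L041_si3	0.94999999999999996	1
L041	L041_si4	1	1
L041	L041_si5	1	1
L042	L042_si1	0.94999999999999996	1
L042	L042_si2	0.94999999999999996	1
L042	L042_si3	0.94999999999999996	1
L042	L042_si4	1	1
L042	L042_si5	1	1
L043	L043_si1	0.94999999999999996	1
L043	L043_si2	0.94999999999999996	1
L043	L043_si3	0.94999999999999996	1
L043	L043_si4	1	1
L043	L043_si5	1	1
L044	L044_si1	0.94999999999999996	1
L044	L044_si2	0.94999999999999996	1
L044	L044_si3	0.94999999999999996	1
L044	L044_si4	1	1
L044	L044_si5	1	1
L045	L045_si1	0.94999999999999996	1
L045	L045_si2	0.94999999999999996	1
L045	L045_si3	0.94999999999999996	1
L045	L045_si4	1	1
L045	L045_si5	1	1
L046	L046_si1	0.94999999999999996	1
L046	L046_si2	0.94999999999999996	1
L046	L046_si3	0.94999999999999996	1
L046	L046_si4	1	1
L046	L046_si5	1	1
L047	L047_si1	0.94999999999999996	1
L047	L047_si2	0.94999999999999996	1
L047	L047_si3	0.94999999999999996	1
L047	L047_si4	1	1
L047	L047_si5	1	1
L048	L048_si1	0.94999999999999996	1
L048	L048_si2	0.94999999999999996	1
L048	L048_si3	0.94999999999999996	1
L048	L048_si4	1	1
L048	L048_si5	1	1
L049	L049_si1	0.94999999999999996	1
L049	L049_si2	0.94999999999999996	1
L049	L049_si3	0.94999999999999996	1
L049	L049_si4	1	1
L049	L049_si5	1	1
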