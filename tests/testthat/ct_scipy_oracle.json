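{"pts": [[0.5479120971, -0.1222431205], [0.7171958398, 0.3947360581], [-0.8116453042, 0.9512447033], [0.522279404, 0.5721286106], [-0.7437727346, -0.0992281242], [-0.2584039515, 0.8535299777], [0.2877302402, 0.6455232265], [-0.1131716023, -0.5455225564], [0.109169574, -0.8723654878], [0.655262344, 0.2633287982], [0.5161754802, -0.2909480637], [0.9413960488, 0.7862422426], [0.5567669941, -0.6107225843], [-0.0665579925, -0.9123924684]], "f": [1.8524476683, 1.9054104279, -1.0868116253, 1.608152203, 0.0145477403, -0.2738414893, 1.1666556406, 0.4775807592, 0.4472902081, 1.9410841251, 1.7197227003, 1.5552858334, 1.404186642, 0.0863273665], "q": [[-0.9, -0.9], [-0.75, -0.9], [-0.6, -0.9], [-0.45, -0.9], [-0.3, -0.9], [-0.15, -0.9], [-0.0, -0.9], [0.15, -0.9], [0.3, -0.9], [0.45, -0.9], [0.6, -0.9], [0.75, -0.9], [0.9, -0.9], [-0.9, -0.75], [-0.75, -0.75], [-0.6, -0.75], [-0.45, -0.75], [-0.3, -0.75], [-0.15, -0.75], [-0.0, -0.75], [0.15, -0.75], [0.3, -0.75], [0.45, -0.75], [0.6, -0.75], [0.75, -0.75], [0.9, -0.75], [-0.9, -0.6], [-0.75, -0.6], [-0.6, -0.6], [-0.45, -0.6], [-0.3, -0.6], [-0.15, -0.6], [-0.0, -0.6], [0.15, -0.6], [0.3, -0.6], [0.45, -0.6], [0.6, -0.6], [0.75, -0.6], [0.9, -0.6], [-0.9, -0.45], [-0.75, -0.45], [-0.6, -0.45], [-0.45, -0.45], [-0.3, -0.45], [-0.15, -0.45], [-0.0, -0.45], [0.15, -0.45], [0.3, -0.45], [0.45, -0.45], [0.6, -0.45], [0.75, -0.45], [0.9, -0.45], [-0.9, -0.3], [-0.75, -0.3], [-0.6, -0.3], [-0.45, -0.3], [-0.3, -0.3], [-0.15, -0.3], [-0.0, -0.3], [0.15, -0.3], [0.3, -0.3], [0.45, -0.3], [0.6, -0.3], [0.75, -0.3], [0.9, -0.3], [-0.9, -0.15], [-0.75, -0.15], [-0.6, -0.15], [-0.45, -0.15], [-0.3, -0.15], [-0.15, -0.15], [-0.0, -0.15], [0.15, -0.15], [0.3, -0.15], [0.45, -0.15], [0.6, -0.15], [0.75, -0.15], [0.9, -0.15], [-0.9, -0.0], [-0.75, -0.0], [-0.6, -0.0], [-0.45, -0.0], [-0.3, -0.0], [-0.15, -0.0], [-0.0, -0.0], [0.15, -0.0], [0.3, -0.0], [0.45, -0.0], [0.6, -0.0], [0.75, -0.0], [0.9, -0.0], [-0.9, 0.15], [-0.75, 0.15], [-0.6, 0.15], [-0.45, 0.15], [-0.3, 0.15], [-0.15, 0.15], [-0.0, 0.15], [0.15, 0.15], [0.3, 0.15], [0.45, 0.15], [0.6, 0.15], [0.75, 0.15], [0.9, 0.15], [-0.9, 0.3], [-0.75, 0.3], [-0.6, 0.3], [-0.45, 0.3], [-0.3, 0.3], [-0.15, 0.3], [-0.0, 0.3], [0.15, 0.3], [0.3, 0.3], [0.45, 0.3], [0.6, 0.3], [0.75, 0.3], [0.9, 0.3], [-0.9, 0.45], [-0.75, 0.45], [-0.6, 0.45], [-0.45, 0.45], [-0.3, 0.45], [-0.15, 0.45], [-0.0, 0.45], [0.15, 0.45], [0.3, 0.45], [0.45, 0.45], [0.6, 0.45], [0.75, 0.45], [0.9, 0.45], [-0.9, 0.6], [-0.75, 0.6], [-0.6, 0.6], [-0.45, 0.6], [-0.3, 0.6], [-0.15, 0.6], [-0.0, 0.6], [0.15, 0.6], [0.3, 0.6], [0.45, 0.6], [0.6, 0.6], [0.75, 0.6], [0.9, 0.6], [-0.9, 0.75], [-0.75, 0.75], [-0.6, 0.75], [-0.45, 0.75], [-0.3, 0.75], [-0.15, 0.75], [-0.0, 0.75], [0.15, 0.75], [0.3, 0.75], [0.45, 0.75], [0.6, 0.75], [0.75, 0.75], [0.9, 0.75], [-0.9, 0.9], [-0.75, 0.9], [-0.6, 0.9], [-0.45, 0.9], [-0.3, 0.9], [-0.15, 0.9], [-0.0, 0.9], [0.15, 0.9], [0.3, 0.9], [0.45, 0.9], [0.6, 0.9], [0.75, 0.9], [0.9, 0.9]], "vals": [null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, null, 0.17492162, 0.41634279, 0.65821344, 0.89171316, null, null, null, null, null, null, null, null, 0.15338863, 0.36087205, 0.59125918, 0.82398862, 1.05190723, 1.26992546, null, null, null, null, null, null, 0.13021285, 0.31229277, 0.51482502, 0.74638409, 1.00113718, 1.2408026, 1.46369496, 1.61809483, null, null, null, null, null, 0.23573229, 0.406141, 0.6195071, 0.85594926, 1.10051539, 1.35189515, 1.61717678, 1.75410081, null, null, null, null, 0.12337031, 0.26794669, 0.45390119, 0.67791186, 0.92195156, 1.16802421, 1.42120113, 1.67613412, 1.87098875, null, null, null, -0.02671863, 0.09682049, 0.26013013, 0.45941065, 0.69171912, 0.94471088, 1.19441456, 1.44920091, 1.70800074, 1.94112036, null, null, null, -0.11636549, 0.01631859, 0.20970706, 0.42389827, 0.66376959, 0.92565773, 1.18433603, 1.44049579, 1.70421366, 1.9272918, 1.97183374, null, null, -0.24022597, -0.09333832, 0.09488231, 0.34828431, 0.60148678, 0.86737865, 1.13953418, 1.39869488, 1.66230254, 1.86289327, 1.96253601, null, null, -0.39242673, -0.2440801, -0.0531339, 0.20927252, 0.50230206, 0.78123829, 1.05863071, 1.32605958, 1.57732529, 1.78362877, 1.87967733, null, null, -0.56709444, -0.42821948, -0.22498842, 0.02138314, 0.3420913, 0.65653089, 0.9505387, 1.22485133, 1.48921991, 1.6445215, 1.72963404, null, null, -0.75835573, -0.62656493, -0.43770137, -0.19086641, 0.11268899, 0.43134113, 0.72229181, 0.96136431, 1.1723434, 1.35306925, 1.4915962, 1.58507074, null, -0.9564892, -0.79936522, -0.6048074, -0.30170289, null, null, null, null, null, null, null, null]}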